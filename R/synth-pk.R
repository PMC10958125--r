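#' Two-compartment infusion simulation parameters
#'
#' Parameters of the concentration simulator: a two-compartment disposition
#' model with a constant-rate intravenous infusion, multiplicative
#' lognormal residual error, a lognormal between-subject effect on
#' clearance, and a per-occasion exposure multiplier (the "true" effect of
#' lycopene co-administration on docetaxel exposure). Defaults are chosen
#' to mimic docetaxel-scale disposition at a 75 mg/m2-like absolute dose —
#' exposure in the low thousands of ng·h/mL, a 1-hour infusion, and the
#' 8.5 ng/mL assay quantification limit; they are illustrative, not fitted.
#'
#' @param cl Clearance (L/h).
#' @param v1 Central volume (L).
#' @param q Inter-compartmental clearance (L/h).
#' @param v2 Peripheral volume (L).
#' @param infusion_h Infusion duration (h).
#' @param dose_mg Administered dose (mg).
#' @param residual_cv Lognormal residual coefficient of variation (< 1).
#' @param between_subject_cv Lognormal CV of subject-level clearance.
#' @param occasion_ratio Named multiplier on exposure per occasion
#'   (reference occasion 1).
#' @param lloq Assay lower limit of quantification (ng/mL).
#' @return An object of class `"pk_sim_params"`.
#' @export
pk_sim_params <- function(cl = 46, v1 = 7.4, q = 28, v2 = 55,
                          infusion_h = 1, dose_mg = 140,
                          residual_cv = 0.2, between_subject_cv = 0.3,
                          occasion_ratio = c(alone = 1, combination = 1.1),
                          lloq = 8.5) {
  vals <- c(cl, v1, q, v2, infusion_h, dose_mg, lloq)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK simulation parameters must be positive")
  if (residual_cv < 0 || residual_cv >= 1)
    stop("residual_cv must lie in [0, 1)")
  if (any(occasion_ratio <= 0)) stop("occasion ratios must be positive")
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2, infusion_h = infusion_h,
                 dose_mg = dose_mg, residual_cv = residual_cv,
                 between_subject_cv = between_subject_cv,
                 occasion_ratio = occasion_ratio, lloq = lloq),
            class = "pk_sim_params")
}

#' Noiseless two-compartment infusion concentration
#'
#' Closed-form plasma concentration (ng/mL) of a two-compartment model
#' under a constant-rate infusion of `dose_mg` over `infusion_h` hours,
#' evaluated by superposition of the biexponential unit-impulse response.
#' `AUC to infinity equals dose/CL` exactly.
#'
#' @param t Time(s) in hours from infusion start.
#' @param params A [pk_sim_params()].
#' @param cl Optional clearance override (L/h), e.g. for per-subject or
#'   per-occasion effects.
#' @return Concentrations in ng/mL (vectorised over `t`).
#' @export
conc_2cmt_infusion <- function(t, params, cl = params$cl) {
  k10 <- cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  A <- (al - k21) / (al - be)
  B <- (k21 - be) / (al - be)
  r0 <- params$dose_mg / params$infusion_h       # mg/h
  tinf <- params$infusion_h
  one <- function(tt) {
    if (tt <= 0) return(0)
    if (tt <= tinf) {
      (r0 / params$v1) * (A / al * (1 - exp(-al * tt)) +
                          B / be * (1 - exp(-be * tt)))
    } else {
      (r0 / params$v1) * (A / al * (1 - exp(-al * tinf)) * exp(-al * (tt - tinf)) +
                          B / be * (1 - exp(-be * tinf)) * exp(-be * (tt - tinf)))
    }
  }
  1000 * vapply(t, one, 0)    # mg/L -> ng/mL
}

#' Generate subject-occasion concentration profiles
#'
#' Simulates paired concentration-time profiles at the protocol sampling
#' times (pre-infusion and 0.5, 0.75, 1, 2, 4, 8, 12, 24 h after infusion
#' start): a subject-level lognormal effect on clearance, the per-occasion
#' exposure multiplier applied as a clearance divisor, and multiplicative
#' lognormal residual error on each sample. Values below the LLOQ are
#' flagged below-quantification by [conc_profile()]. The same seed yields
#' identical profiles.
#'
#' @param params A [pk_sim_params()].
#' @param n_subjects Number of subjects.
#' @param occasions Character vector of occasions; must name entries of
#'   `params$occasion_ratio`.
#' @param times Sampling times (h).
#' @param seed Integer seed.
#' @return A list of [conc_profile()] objects.
#' @export
generate_pk_profiles <- function(params, n_subjects = 6,
                                 occasions = c("alone", "combination"),
                                 times = c(0, 0.5, 0.75, 1, 2, 4, 8, 12, 24),
                                 seed = 1L) {
  stopifnot(inherits(params, "pk_sim_params"))
  if (!all(occasions %in% names(params$occasion_ratio)))
    stop("every occasion must have an entry in params$occasion_ratio")
  sd_bs <- sqrt(log(1 + params$between_subject_cv^2))
  sd_res <- sqrt(log(1 + params$residual_cv^2))
  out <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(.derive_seed(seed, i))
    cl_i <- params$cl * exp(stats::rnorm(1, 0, sd_bs))
    for (o in occasions) {
      cl_io <- cl_i / params$occasion_ratio[[o]]
      c_true <- conc_2cmt_infusion(times, params, cl = cl_io)
      eps <- if (sd_res > 0) exp(stats::rnorm(length(times), 0, sd_res)) else 1
      obs <- c_true * eps
      out[[length(out) + 1L]] <-
        conc_profile(paste0("S", i), o, times, obs, params$dose_mg,
                     params$lloq)
    }
  }
  out
}

#' Flatten concentration profiles to a delimited-text table
#'
#' Produces the long CSV dialect accepted by [read_pk_data()]; below-LLOQ
#' samples are written as the string `"BLQ"`.
#'
#' @param profiles A list of [conc_profile()] objects.
#' @return A data frame with columns
#'   `subject,occasion,time_h,conc_ng_ml,dose_mg,lloq_ng_ml`.
#' @export
pk_profiles_to_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    data.frame(subject = p$subject, occasion = p$occasion,
               time_h = p$time_h,
               conc_ng_ml = ifelse(p$blq, "BLQ",
                                   format(p$conc, digits = 10)),
               dose_mg = p$dose_mg, lloq_ng_ml = p$lloq)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
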