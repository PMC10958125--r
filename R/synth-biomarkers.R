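#' Biomarker trajectory simulation parameters
#'
#' Group-level shapes for the longitudinal correlative measurements, one
#' setting per lycopene dose group (30, 90, 150 mg/day), on the protocol
#' observation days (1, 15, 36, 57, 78, 99):
#'
#' * plasma lycopene rises from baseline toward a plateau, faster at the
#'   higher doses but with a common plateau level (the saturation seen at
#'   90 mg/day and above);
#' * VEGF-A follows a log-linear time trend whose slope flips sign with
#'   dose — negative at 30 mg/day, near zero at 90, positive at 150;
#' * circulating endothelial cells show a transient log-scale excursion
#'   peaking at `cec_peak_day`, downward in the 30 mg/day group and upward
#'   at 90/150 (larger at 90);
#' * the ligand-dependent IGF-1R phosphorylation ratio is flat except for a
#'   late decline (days 78 and 99) in the top dose group;
#' * PSA declines from baseline toward a subject-specific nadir.
#'
#' All noise is multiplicative lognormal (positive, skewed measurements).
#'
#' @param lycopene_baseline Baseline plasma lycopene (µmol/L).
#' @param lycopene_plateau Plateau plasma lycopene (µmol/L).
#' @param lycopene_rise_rate Per-group rise rate (1/day), names "30","90","150".
#' @param vegf_baseline Baseline VEGF-A (pg/mL).
#' @param vegf_log_slope Per-group VEGF-A log-slope (1/day).
#' @param cec_baseline Baseline CEC count (cells/4 mL).
#' @param cec_peak_day Day of the CEC excursion peak.
#' @param cec_log_amplitude Per-group log-scale excursion amplitude.
#' @param cec_width_days Gaussian width of the excursion (days).
#' @param pigf_baseline_ratio Baseline stimulated/unstimulated ratio.
#' @param pigf_late_log_drop Log fold applied at days 78/99 in the 150
#'   mg/day group (length 2).
#' @param psa_baseline_median Median baseline PSA (µg/L).
#' @param psa_baseline_sdlog Lognormal sdlog of baseline PSA.
#' @param psa_nadir_mu,psa_nadir_sd Normal parameters of log nadir fraction.
#' @param noise_cv Lognormal noise CV shared by the analytes.
#' @return An object of class `"biomarker_sim_params"`.
#' @export
biomarker_sim_params <- function(
    lycopene_baseline = 0.48, lycopene_plateau = 0.82,
    lycopene_rise_rate = c("30" = 0.02, "90" = 0.05, "150" = 0.08),
    vegf_baseline = 353,
    vegf_log_slope = c("30" = -0.005, "90" = 0, "150" = 0.005),
    cec_baseline = 788, cec_peak_day = 57,
    cec_log_amplitude = c("30" = -0.7, "90" = 1.0, "150" = 0.6),
    cec_width_days = 25,
    pigf_baseline_ratio = 10.9,
    pigf_late_log_drop = c(-0.35, -0.55),
    psa_baseline_median = 19.2, psa_baseline_sdlog = 1.3,
    psa_nadir_mu = log(0.28), psa_nadir_sd = 0.8,
    noise_cv = 0.25) {
  if (lycopene_plateau <= 0 || lycopene_baseline <= 0)
    stop("lycopene levels must be positive")
  if (noise_cv < 0 || noise_cv >= 1) stop("noise_cv must lie in [0, 1)")
  structure(list(
    lycopene_baseline = lycopene_baseline,
    lycopene_plateau = lycopene_plateau,
    lycopene_rise_rate = lycopene_rise_rate,
    vegf_baseline = vegf_baseline, vegf_log_slope = vegf_log_slope,
    cec_baseline = cec_baseline, cec_peak_day = cec_peak_day,
    cec_log_amplitude = cec_log_amplitude, cec_width_days = cec_width_days,
    pigf_baseline_ratio = pigf_baseline_ratio,
    pigf_late_log_drop = pigf_late_log_drop,
    psa_baseline_median = psa_baseline_median,
    psa_baseline_sdlog = psa_baseline_sdlog,
    psa_nadir_mu = psa_nadir_mu, psa_nadir_sd = psa_nadir_sd,
    noise_cv = noise_cv), class = "biomarker_sim_params")
}

# noiseless group-level trajectories on a vector of days
.traj_lycopene <- function(p, days, grp)
  p$lycopene_baseline + (p$lycopene_plateau - p$lycopene_baseline) *
    (1 - exp(-p$lycopene_rise_rate[[grp]] * pmax(0, days - 1)))

.traj_vegf <- function(p, days, grp)
  p$vegf_baseline * exp(p$vegf_log_slope[[grp]] * (days - 1))

.traj_cec <- function(p, days, grp)
  p$cec_baseline * exp(p$cec_log_amplitude[[grp]] *
    exp(-((days - p$cec_peak_day) / p$cec_width_days)^2) *
    ifelse(days <= 1, 0, 1))

.traj_pigf_ratio <- function(p, days, grp) {
  f <- rep(1, length(days))
  if (grp == "150") {
    f[days == 78] <- exp(p$pigf_late_log_drop[1L])
    f[days == 99] <- exp(p$pigf_late_log_drop[2L])
  }
  p$pigf_baseline_ratio * f
}

#' Generate a coherent correlative-biomarker panel
#'
#' Simulates the full correlative dataset for a cohort: long-format
#' biomarker series (plasma lycopene, VEGF-A, CEC), the phospho-assay table
#' (stimulated and unstimulated signals whose ratio carries the
#' ligand-dependent phosphorylation trajectory), and per-subject PSA
#' series. Trajectories follow the configured group shapes with lognormal
#' noise; every table is a pure function of `(params, n_per_group, seed)`.
#'
#' @param params A [biomarker_sim_params()].
#' @param n_per_group Named integer vector of subjects per dose group
#'   (mg/day), default `c("30" = 3, "90" = 3, "150" = 6)`.
#' @param days Observation days.
#' @param seed Integer seed.
#' @return A list of data frames: `biomarkers`
#'   (`subject,dose_group,analyte,day,value`), `phospho`
#'   (`subject,dose_group,day,stimulated,unstimulated`), `psa`
#'   (`subject,dose_group,baseline,day,value`).
#' @export
generate_biomarker_panel <- function(params,
                                     n_per_group = c("30" = 3, "90" = 3,
                                                     "150" = 6),
                                     days = c(1, 15, 36, 57, 78, 99),
                                     seed = 1L) {
  stopifnot(inherits(params, "biomarker_sim_params"))
  sd_n <- sqrt(log(1 + params$noise_cv^2))
  noise <- function(k) if (sd_n > 0) exp(stats::rnorm(k, 0, sd_n)) else rep(1, k)
  bm <- ph <- psa <- list()
  sid <- 0L
  for (grp in names(n_per_group)) {
    for (i in seq_len(n_per_group[[grp]])) {
      sid <- sid + 1L
      subject <- sprintf("B%02d", sid)
      set.seed(.derive_seed(seed, sid))
      add <- function(analyte, traj) {
        data.frame(subject = subject, dose_group = as.numeric(grp),
                   analyte = analyte, day = days, value = traj * noise(length(days)))
      }
      bm[[length(bm) + 1L]] <- add("lycopene", .traj_lycopene(params, days, grp))
      bm[[length(bm) + 1L]] <- add("vegf_a", .traj_vegf(params, days, grp))
      bm[[length(bm) + 1L]] <- add("cec", .traj_cec(params, days, grp))
      unstim <- noise(length(days))
      ratio <- .traj_pigf_ratio(params, days, grp) * noise(length(days))
      ph[[length(ph) + 1L]] <- data.frame(
        subject = subject, dose_group = as.numeric(grp), day = days,
        stimulated = unstim * ratio, unstimulated = unstim)
      base <- stats::rlnorm(1, log(params$psa_baseline_median),
                            params$psa_baseline_sdlog)
      nadir_frac <- min(exp(stats::rnorm(1, params$psa_nadir_mu,
                                         params$psa_nadir_sd)), 1.5)
      fu_days <- days[-1L]
      frac <- nadir_frac + (1 - nadir_frac) * exp(-0.04 * (fu_days - 1))
      psa[[length(psa) + 1L]] <- data.frame(
        subject = subject, dose_group = as.numeric(grp),
        baseline = base, day = fu_days,
        value = base * frac * noise(length(fu_days)))
    }
  }
  list(biomarkers = do.call(rbind, bm),
       phospho = do.call(rbind, ph),
       psa = do.call(rbind, psa))
}
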