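#' Concentration-time profile
#'
#' One subject-occasion concentration-time series for non-compartmental
#' analysis. Concentrations below the assay's lower limit of quantification
#' (LLOQ) are flagged rather than carried as numbers: samples before the
#' first quantifiable concentration are treated as zero, and embedded or
#' trailing BLQ samples are excluded from AUC and terminal-slope fitting.
#'
#' @param subject Subject identifier.
#' @param occasion Occasion label, e.g. `"alone"` or `"combination"`.
#' @param time_h Sample times in hours post infusion start; strictly
#'   increasing, non-negative; at least 3 samples.
#' @param conc Concentrations in ng/mL. `NA` or negative values are
#'   interpreted as below-LLOQ, as are values under `lloq`.
#' @param dose_mg Administered dose in mg.
#' @param lloq Lower limit of quantification in ng/mL (docetaxel assay
#'   default 8.5).
#' @return An object of class `"conc_profile"`.
#' @export
conc_profile <- function(subject, occasion, time_h, conc, dose_mg,
                         lloq = 8.5) {
  time_h <- as.numeric(time_h); conc <- as.numeric(conc)
  if (length(time_h) != length(conc))
    stop("time_h and conc must have equal length")
  if (length(time_h) < 3L) stop("a profile needs at least 3 samples")
  if (any(time_h < 0) || any(diff(time_h) <= 0))
    stop("sample times must be non-negative and strictly increasing")
  if (!is.numeric(dose_mg) || dose_mg <= 0) stop("dose_mg must be positive")
  blq <- is.na(conc) | conc < lloq
  conc[blq] <- NA_real_
  structure(list(subject = subject, occasion = occasion, time_h = time_h,
                 conc = conc, blq = blq, dose_mg = dose_mg, lloq = lloq),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("conc_profile: subject %s, occasion %s, dose %g mg, %d samples (%d BLQ)\n",
              x$subject, x$occasion, x$dose_mg, length(x$time_h), sum(x$blq)))
  invisible(x)
}

# concentrations with the BLQ policy applied for integration:
# leading BLQ -> 0, embedded/trailing BLQ -> dropped
.auc_points <- function(profile) {
  q <- which(!profile$blq)
  if (!length(q)) return(NULL)
  first_q <- q[1L]
  keep_lead <- seq_len(first_q - 1L)
  t <- c(profile$time_h[keep_lead], profile$time_h[q])
  c_ <- c(rep(0, length(keep_lead)), profile$conc[q])
  list(t = t, c = c_)
}

#' Peak concentration and its time
#'
#' Maximum observed quantifiable concentration and the earliest time at
#' which it occurs.
#'
#' @param profile A [conc_profile()].
#' @return A list with `cmax` (ng/mL) and `tmax` (h); both `NA` with a
#'   warning when every sample is below the LLOQ.
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  q <- which(!profile$blq)
  if (!length(q)) {
    warning("all samples below LLOQ; no Cmax")
    return(list(cmax = NA_real_, tmax = NA_real_))
  }
  cm <- max(profile$conc[q])
  list(cmax = cm, tmax = profile$time_h[q[profile$conc[q] == cm][1L]])
}

#' AUC to the last quantifiable concentration
#'
#' Trapezoidal area under the concentration-time curve from time zero to
#' the last quantifiable sample. `"linear"` uses the linear trapezoid on
#' every interval; `"linuplogdown"` (default, standard practice for
#' post-peak decline) uses the log trapezoid
#' `(C1 - C2) * dt / log(C1/C2)` on intervals where the concentration
#' falls between two positive samples, and the linear rule otherwise.
#'
#' @param profile A [conc_profile()].
#' @param method `"linuplogdown"` or `"linear"`.
#' @return AUC_last in ng·h/mL; `NA` with a warning when fewer than two
#'   quantifiable samples exist.
#' @export
auc_last <- function(profile, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_profile"))
  pts <- .auc_points(profile)
  if (is.null(pts) || sum(!profile$blq) < 2L) {
    warning("fewer than 2 quantifiable samples; no AUC")
    return(NA_real_)
  }
  t <- pts$t; c_ <- pts$c
  auc <- 0
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    c1 <- c_[i]; c2 <- c_[i + 1L]
    if (method == "linuplogdown" && c2 < c1 && c2 > 0) {
      auc <- auc + dt * (c1 - c2) / log(c1 / c2)
    } else {
      auc <- auc + dt * (c1 + c2) / 2
    }
  }
  auc
}

#' Terminal elimination rate constant
#'
#' Log-linear least-squares fit to the terminal phase. Candidate point sets
#' are the last `m` quantifiable samples strictly after Tmax (Tmax itself
#' excluded), for `m` from 3 up to all eligible points; the set maximising
#' the adjusted R-squared is selected (ties toward more points). The rate
#' is the negative of the fitted slope.
#'
#' @param profile A [conc_profile()].
#' @return A list with `lambda_z` (1/h), `n_points`, `adj_r2`, and
#'   `t_points` (the times used); all `NA` with a warning when fewer than
#'   3 eligible points exist or no candidate has a negative slope.
#' @export
fit_lambda_z <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  no_fit <- list(lambda_z = NA_real_, n_points = NA_integer_,
                 adj_r2 = NA_real_, t_points = NULL)
  ct <- cmax_tmax(profile)
  if (is.na(ct$cmax)) return(no_fit)
  q <- which(!profile$blq & profile$time_h > ct$tmax & profile$conc > 0)
  if (length(q) < 3L) {
    warning("fewer than 3 quantifiable post-Tmax samples; no lambda_z")
    return(no_fit)
  }
  t <- profile$time_h[q]; lc <- log(profile$conc[q])
  best <- NULL
  for (m in 3:length(q)) {
    idx <- seq.int(length(q) - m + 1L, length(q))
    fit <- stats::lm.fit(cbind(1, t[idx]), lc[idx])
    slope <- unname(fit$coefficients[2L])
    if (slope >= 0) next
    r2 <- 1 - sum(fit$residuals^2) / sum((lc[idx] - mean(lc[idx]))^2)
    adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (is.null(best) || adj >= best$adj_r2 - 1e-12)
      best <- list(lambda_z = -slope, n_points = m, adj_r2 = adj,
                   t_points = t[idx])
  }
  if (is.null(best)) {
    warning("no candidate terminal set with negative slope; no lambda_z")
    return(no_fit)
  }
  best
}

#' Full non-compartmental summary of one profile
#'
#' Combines [cmax_tmax()], [auc_last()] and [fit_lambda_z()] into the
#' standard NCA parameter set with extrapolation to infinite time:
#' `AUC_inf = AUC_last + C_last / lambda_z`. A message is emitted when the
#' extrapolated fraction exceeds 20%, the conventional reliability bound.
#' Dose-normalised variants divide by the administered dose in mg.
#'
#' @inheritParams auc_last
#' @return A one-row data frame of class `"nca_result"`: `subject`,
#'   `occasion`, `dose_mg`, `cmax`, `tmax`, `auc_last`, `lambda_z`,
#'   `lambda_z_n_points`, `lambda_z_adj_r2`, `auc_inf`,
#'   `extrapolated_fraction`, `cmax_dn`, `auc_last_dn`, `auc_inf_dn`.
#' @examples
#' p <- conc_profile("s1", "alone", c(0.5, 1, 2, 4, 8, 24),
#'                   1000 * exp(-0.3 * c(0.5, 1, 2, 4, 8, 24)),
#'                   dose_mg = 140)
#' nca(p)
#' @export
nca <- function(profile, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  ct <- cmax_tmax(profile)
  al <- auc_last(profile, method)
  lz <- fit_lambda_z(profile)
  if (!is.na(al) && !is.na(lz$lambda_z)) {
    q <- which(!profile$blq)
    c_last <- profile$conc[q[length(q)]]
    ai <- al + c_last / lz$lambda_z
    ef <- 1 - al / ai
    if (ef > 0.2)
      message(sprintf("profile %s/%s: extrapolated fraction %.1f%% exceeds 20%%",
                      profile$subject, profile$occasion, 100 * ef))
  } else {
    ai <- NA_real_; ef <- NA_real_
  }
  out <- data.frame(
    subject = profile$subject, occasion = profile$occasion,
    dose_mg = profile$dose_mg,
    cmax = ct$cmax, tmax = ct$tmax, auc_last = al,
    lambda_z = lz$lambda_z, lambda_z_n_points = lz$n_points,
    lambda_z_adj_r2 = lz$adj_r2,
    auc_inf = ai, extrapolated_fraction = ef,
    cmax_dn = ct$cmax / profile$dose_mg,
    auc_last_dn = al / profile$dose_mg,
    auc_inf_dn = ai / profile$dose_mg)
  class(out) <- c("nca_result", "data.frame")
  out
}

#' Read concentration-time data from delimited text
#'
#' Expects columns `subject,occasion,time_h,conc_ng_ml,dose_mg,lloq_ng_ml`.
#' BLQ samples may be encoded as the string `"BLQ"`, as negative sentinels,
#' or as empty fields; all are normalised to flagged below-LLOQ samples.
#'
#' @param path File path.
#' @return A list of [conc_profile()] objects, one per subject-occasion.
#' @export
read_pk_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "occasion", "time_h", "conc_ng_ml", "dose_mg",
              "lloq_ng_ml")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("file ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  raw <- df$conc_ng_ml
  conc <- suppressWarnings(as.numeric(raw))
  conc[!is.na(raw) & toupper(trimws(as.character(raw))) == "BLQ"] <- -1
  conc[is.na(conc)] <- -1
  df$conc_ng_ml <- conc
  key <- interaction(df$subject, df$occasion, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    conc_profile(d$subject[1L], d$occasion[1L], d$time_h, d$conc_ng_ml,
                 d$dose_mg[1L], d$lloq_ng_ml[1L])
  })
}

#' Write per-subject NCA results to CSV
#'
#' @param results A data frame of stacked [nca()] rows.
#' @param path File path.
#' @export
write_nca_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
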