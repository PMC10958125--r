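#' Baseline fold-change normalisation
#'
#' Divides each value in a longitudinal series by its day-1 (baseline)
#' value, so the baseline maps to 1. This is the normalisation applied to
#' circulating endothelial cell counts, VEGF-A and the phosphorylation
#' ratio before any inference.
#'
#' @param values Positive numeric vector of measurements.
#' @param days Observation days, same length; must contain `baseline_day`.
#' @param baseline_day Day defining the baseline (default 1).
#' @return Numeric vector of fold changes in the order of `values`.
#' @examples
#' fold_change(c(788, 1576), c(1, 57))   # 1, 2
#' @export
fold_change <- function(values, days, baseline_day = 1) {
  if (length(values) != length(days)) stop("values and days must align")
  i <- which(days == baseline_day)
  if (length(i) != 1L)
    stop("exactly one baseline (day ", baseline_day, ") value is required")
  if (is.na(values[i]) || values[i] <= 0)
    stop("baseline value must be present and positive")
  values / values[i]
}

#' Ligand-dependent IGF-1R phosphorylation ratio
#'
#' The assay readout: the ratio of phospho-IGF-1R(Y1131) signal in
#' ligand-stimulated peripheral blood mononuclear cells to the unstimulated
#' signal from the same sample. Fold change over time is the day-d ratio
#' divided by the day-1 ratio (see [fold_change()]).
#'
#' @param stimulated Positive signal from rhIGF-1-stimulated cells.
#' @param unstimulated Positive signal from unstimulated cells.
#' @return The ratio (vectorised).
#' @examples
#' ligand_dependent_phosphorylation(10.9, 1)   # 10.9
#' @export
ligand_dependent_phosphorylation <- function(stimulated, unstimulated) {
  if (any(stimulated <= 0) || any(unstimulated <= 0))
    stop("phospho-assay signals must be strictly positive")
  stimulated / unstimulated
}

#' Exact Wilcoxon signed-rank test
#'
#' Small-sample exact signed-rank test: zero differences are dropped, tied
#' absolute differences receive mid-ranks, and for `n <= 25` the p-value is
#' computed from the exact null distribution of the positive-rank sum over
#' all `2^n` equiprobable sign assignments (a shift-algorithm enumeration,
#' exact also in the presence of ties). Beyond 25 non-zero differences a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param differences Numeric vector of paired differences.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`. `"less"`
#'   tests for predominantly negative differences.
#' @return A list with `statistic` (positive-rank sum V), `p_value`, `n`
#'   (non-zero differences used), and `exact` (logical).
#' @examples
#' wilcoxon_signed_rank_exact(c(-3, -1, -4, -2, -5), "less")$p_value  # 1/32
#' @export
wilcoxon_signed_rank_exact <- function(differences,
                                       alternative = c("two.sided", "less",
                                                       "greater")) {
  alternative <- match.arg(alternative)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    warning("all differences are zero; test undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                exact = NA))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of 2*V via subset-sum counts over integer
    # doubled ranks (mid-ranks are multiples of 1/2)
    w2 <- as.integer(round(2 * r))
    counts <- numeric(sum(w2) + 1L)   # counts[s+1] = #subsets with sum s
    counts[1L] <- 1
    for (w in w2) {
      shifted <- c(rep(0, w), counts[seq_len(length(counts) - w)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- round(2 * v)
    p_le <- sum(counts[seq_len(v2 + 1L)]) / total
    p_ge <- sum(counts[seq.int(v2 + 1L, length(counts))]) / total
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z_le <- (v - mu + 0.5) / sqrt(sigma2)
    z_ge <- (v - mu - 0.5) / sqrt(sigma2)
    p_le <- stats::pnorm(z_le)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    exact <- FALSE
  }
  list(statistic = v, p_value = p, n = n, exact = exact)
}

#' One-sided paired t test
#'
#' Classical paired t on the differences `y - x` with a one-sided
#' alternative, computed from the textbook formula
#' `t = mean(d) / (sd(d)/sqrt(n))` on `n - 1` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (`n >= 2`).
#' @param direction `"greater"` tests `y > x`; `"less"` tests `y < x`;
#'   `"two.sided"` also available.
#' @return A list with `t`, `df`, `p_value`, `mean_difference`. When the
#'   differences have zero variance the statistic is undefined and the
#'   result is flagged with `NA` and a warning.
#' @export
paired_t_one_sided <- function(x, y, direction = c("greater", "less",
                                                   "two.sided")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("paired test requires equal lengths")
  d <- y - x
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("at least 2 complete pairs are required")
  s <- stats::sd(d)
  if (s == 0) {
    warning("differences have zero variance; t statistic undefined")
    return(list(t = NA_real_, df = n - 1L, p_value = NA_real_,
                mean_difference = mean(d)))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- switch(direction,
              greater = stats::pt(t, n - 1L, lower.tail = FALSE),
              less = stats::pt(t, n - 1L),
              two.sided = 2 * stats::pt(-abs(t), n - 1L))
  list(t = t, df = n - 1L, p_value = p, mean_difference = mean(d))
}

#' PSA response classification
#'
#' Percent change from baseline PSA to the nadir (minimum) of all recorded
#' follow-up values; a reduction of at least 50% from baseline counts as a
#' response (the boundary is inclusive).
#'
#' @param baseline Baseline PSA in µg/L (> 0).
#' @param followups Numeric vector of follow-up PSA values (>= 1 value).
#' @return A list with `nadir`, `percent_change` and `responder`.
#' @examples
#' psa_response(100, c(80, 27.19, 35))   # -72.81%, responder
#' @export
psa_response <- function(baseline, followups) {
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("baseline PSA must be a single positive value")
  followups <- followups[!is.na(followups)]
  if (!length(followups)) stop("at least one follow-up PSA value is required")
  nadir <- min(followups)
  pc <- (nadir - baseline) / baseline * 100
  list(nadir = nadir, percent_change = pc, responder = pc <= -50)
}

#' Read a long-format biomarker table
#'
#' Expects columns `subject,dose_group,analyte,day,value`; rows for the
#' phospho assay may instead carry `stimulated` and `unstimulated` columns,
#' in which case `value` is derived as their ratio.
#'
#' @param path File path.
#' @return A data frame ordered by subject, analyte, day.
#' @export
read_biomarker_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("stimulated", "unstimulated") %in% names(df)) &&
      !"value" %in% names(df))
    df$value <- ligand_dependent_phosphorylation(df$stimulated,
                                                 df$unstimulated)
  needed <- c("subject", "dose_group", "analyte", "day", "value")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("file ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  df[order(df$subject, df$analyte, df$day), needed]
}

#' Fold-change table for a biomarker panel
#'
#' Applies [fold_change()] within each subject-analyte series of a
#' long-format biomarker table.
#'
#' @param data A data frame with `subject,dose_group,analyte,day,value`.
#' @param baseline_day Baseline day (default 1).
#' @return The input with an added `fold_change` column.
#' @export
biomarker_fold_changes <- function(data, baseline_day = 1) {
  data <- as.data.frame(data)
  key <- interaction(data$subject, data$analyte, drop = TRUE)
  parts <- lapply(split(data, key), function(d) {
    d$fold_change <- fold_change(d$value, d$day, baseline_day)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$subject, out$analyte, out$day), ]
}
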