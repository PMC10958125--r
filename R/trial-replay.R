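#' Patient enrollment records
#'
#' Validates a data frame of enrollment records with columns `patient_id`,
#' `enrollment_order`, `dose_level`, `dlt`, `evaluable`. Non-evaluable
#' records (withdrawal before DLT assessment) contribute nothing to the
#' toxicity tally.
#'
#' @param records A data frame with the columns above.
#' @param n_levels Number of dose levels in the grid the records refer to.
#' @return The validated data frame, ordered by `enrollment_order`, with
#'   class `c("patient_records", "data.frame")`.
#' @export
patient_records <- function(records, n_levels = 3L) {
  needed <- c("patient_id", "enrollment_order", "dose_level", "dlt", "evaluable")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[, needed]
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$dose_level) || r$dose_level < 1 || r$dose_level > n_levels)
      stop("record ", i, ": dose_level ", r$dose_level,
           " outside the ", n_levels, "-level grid")
    if (!r$dlt %in% c(0, 1))
      stop("record ", i, ": dlt must be 0/1")
    if (!r$evaluable %in% c(0, 1))
      stop("record ", i, ": evaluable must be 0/1")
  }
  records$dlt <- as.logical(records$dlt)
  records$evaluable <- as.logical(records$evaluable)
  records <- records[order(records$enrollment_order), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("patient_records", "data.frame")
  records
}

#' Reconstructed enrollment sequence of the escalation cohort
#'
#' The dose-escalation enrollment sequence implied by the published
#' per-patient escalation trace: three patients at level 1 (30 mg/day, no
#' DLT), three at level 2 (90 mg/day, no DLT), and twelve at level 3
#' (150 mg/day) of whom one (patient 13) withdrew before DLT assessment and
#' one (patient 14, the 13th evaluable patient) had the single DLT. This
#' sequence is a reconstruction from the printed trace, not a deposited
#' patient-level dataset.
#'
#' @return A [patient_records()] data frame with 18 rows.
#' @export
study_enrollment <- function() {
  patient_records(data.frame(
    patient_id = 1:18,
    enrollment_order = 1:18,
    dose_level = c(rep(1L, 3), rep(2L, 3), rep(3L, 12)),
    dlt = c(rep(FALSE, 13), TRUE, rep(FALSE, 4)),
    evaluable = c(rep(TRUE, 12), FALSE, rep(TRUE, 5))
  ))
}

# accumulate evaluable records into a toxicity_tally
.records_to_tally <- function(records, n_levels) {
  n <- integer(n_levels); y <- integer(n_levels)
  ev <- records[records$evaluable, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    j <- ev$dose_level[i]
    n[j] <- n[j] + 1L
    y[j] <- y[j] + as.integer(ev$dlt[i])
  }
  toxicity_tally(n, y)
}

#' Replay a recorded escalation
#'
#' Regenerates the sequential escalation trace from an ordered enrollment
#' record: for each evaluable patient, the model-averaged toxicity
#' estimates computed from the evaluable patients enrolled before them, and
#' a final row on the full data. With `cadence = "per-patient"` the
#' posterior is recomputed before every patient; with `"per-cohort"` it is
#' refreshed only when the preceding evaluable count completes a cohort, so
#' rows within a cohort repeat the estimates in force when the cohort
#' opened.
#'
#' @param model A [bma_crm_model()].
#' @param records A [patient_records()] data frame (or coercible).
#' @param cadence `"per-patient"` (default) or `"per-cohort"`.
#' @return A data frame of class `"escalation_trace"` with one row per
#'   evaluable patient plus a final row: `order`, `patient_id`, `n_used`,
#'   `pi_hat_1..K`, `p_overdose_lowest`, `assigned_level`, `decision`.
#' @examples
#' m <- bma_crm_model()
#' tr <- replay_trial(m, study_enrollment())
#' tr[c(1, nrow(tr)), ]
#' @export
replay_trial <- function(model, records,
                         cadence = c("per-patient", "per-cohort")) {
  cadence <- match.arg(cadence)
  stopifnot(inherits(model, "bma_crm_model"))
  K <- length(model$dose_grid)
  if (!inherits(records, "patient_records"))
    records <- patient_records(records, K)

  rows <- list()
  current <- NULL      # posterior in force
  n_at_last_update <- -1L

  emit <- function(order, pid, n_used, post, assigned, decision) {
    r <- c(list(order = order, patient_id = pid, n_used = n_used),
           stats::setNames(as.list(post$pi_hat), paste0("pi_hat_", seq_len(K))),
           list(p_overdose_lowest = post$p_lowest_overdose,
                assigned_level = assigned, decision = decision))
    as.data.frame(r)
  }

  seen <- records[0, , drop = FALSE]
  order_out <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    n_ev <- sum(seen$evaluable)
    refresh <- cadence == "per-patient" || n_ev %% model$cohort_size == 0L ||
      is.null(current)
    if (refresh && n_ev != n_at_last_update) {
      current <- bma_toxicity_estimates(model, .records_to_tally(seen, K))
      n_at_last_update <- n_ev
    }
    if (rec$evaluable) {
      order_out <- order_out + 1L
      decision <- if (current$p_lowest_overdose > model$overdose_threshold)
        "terminate" else "dose"
      rows[[length(rows) + 1L]] <-
        emit(order_out, rec$patient_id, n_ev, current, rec$dose_level, decision)
    }
    seen <- rbind(seen, rec)
  }
  final <- bma_toxicity_estimates(model, .records_to_tally(seen, K))
  rows[[length(rows) + 1L]] <-
    emit(order_out + 1L, NA_integer_, sum(seen$evaluable), final,
         NA_integer_, "final")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("escalation_trace", "data.frame")
  out
}

#' Read and write trial records and traces as delimited text
#'
#' `read_trial_records()` expects a CSV with header
#' `patient_id,enrollment_order,dose_level,dlt,evaluable` (booleans as
#' 0/1) and validates each row, reporting the offending line on error.
#' `write_trial_records()` and `write_trace()` are the inverses;
#' `read(write(x))` round-trips exactly.
#'
#' @param path File path.
#' @param n_levels Number of dose levels for validation.
#' @return `read_trial_records()` returns a [patient_records()] data frame.
#' @export
read_trial_records <- function(path, n_levels = 3L) {
  df <- utils::read.csv(path)
  needed <- c("patient_id", "enrollment_order", "dose_level", "dlt", "evaluable")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("file ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    if (!df$dlt[i] %in% c(0, 1) || !df$evaluable[i] %in% c(0, 1))
      stop("file ", path, " line ", i + 1L, ": dlt/evaluable must be 0/1")
    if (is.na(df$dose_level[i]) || df$dose_level[i] < 1 ||
        df$dose_level[i] > n_levels)
      stop("file ", path, " line ", i + 1L, ": dose_level ",
           df$dose_level[i], " outside the ", n_levels, "-level grid")
  }
  patient_records(df, n_levels)
}

#' @rdname read_trial_records
#' @param records A [patient_records()] data frame.
#' @export
write_trial_records <- function(records, path) {
  df <- as.data.frame(records)
  df$dlt <- as.integer(df$dlt)
  df$evaluable <- as.integer(df$evaluable)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trial_records
#' @param trace An `"escalation_trace"` data frame from [replay_trial()].
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
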