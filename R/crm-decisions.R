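#' Early-termination rule
#'
#' The trial stops early when the lowest dose is found excessively toxic:
#' `Pr(pi_1 > target | data) > overdose_threshold`.
#'
#' @inheritParams model_weights
#' @return `TRUE` if the stopping rule fires.
#' @export
should_terminate <- function(model, tally) {
  overdose_probability_lowest_dose(model, tally) > model$overdose_threshold
}

#' Dose assignment for the next patient
#'
#' Assigns the dose whose estimated toxicity probability is closest to the
#' target, without skipping: the assignment may be at most one level above
#' the highest dose already tried. At trial start (no dose tried yet) the
#' assignment is level 1. If the early-termination rule fires, the decision
#' is `"terminate"`.
#'
#' @inheritParams model_weights
#' @param highest_tried Highest dose level tried so far (integer index), or
#'   `NULL` at trial start.
#' @return A list with `decision` (`"dose"` or `"terminate"`), `level`
#'   (integer or `NA`), and the `posterior` summary used.
#' @export
next_dose <- function(model, tally, highest_tried = NULL) {
  stopifnot(inherits(model, "bma_crm_model"))
  K <- length(model$dose_grid)
  if (is.null(highest_tried))
    return(list(decision = "dose", level = 1L, posterior = NULL))
  highest_tried <- as.integer(highest_tried)
  if (highest_tried < 1L || highest_tried > K)
    stop("highest_tried must index a dose level in the grid")
  post <- bma_toxicity_estimates(model, tally)
  if (post$p_lowest_overdose > model$overdose_threshold)
    return(list(decision = "terminate", level = NA_integer_, posterior = post))
  eligible <- seq_len(min(K, highest_tried + 1L))
  dist <- abs(post$pi_hat[eligible] - model$target_toxicity)
  # ties broken toward the higher dose
  best <- max(eligible[dist <= min(dist) + 1e-12])
  list(decision = "dose", level = best, posterior = post)
}

#' Maximum tolerated dose selection
#'
#' The MTD is the highest dose level whose final estimated toxicity
#' probability is closest to the target (ties broken toward the higher
#' dose). If the early-termination rule fires on the final data, no MTD is
#' declared.
#'
#' @inheritParams model_weights
#' @return A list of class `"mtd_selection"` with `decision` (`"mtd"` or
#'   `"terminate"`), `level`, `dose` (mg/day), and the final `posterior`.
#' @examples
#' m <- bma_crm_model()
#' select_mtd(m, toxicity_tally(c(3, 3, 11), c(0, 0, 1)))
#' @export
select_mtd <- function(model, tally) {
  stopifnot(inherits(model, "bma_crm_model"), inherits(tally, "toxicity_tally"))
  if (sum(tally$n) < 1L)
    stop("MTD selection requires at least one treated evaluable patient")
  post <- bma_toxicity_estimates(model, tally)
  if (post$p_lowest_overdose > model$overdose_threshold)
    return(structure(list(decision = "terminate", level = NA_integer_,
                          dose = NA_real_, posterior = post),
                     class = "mtd_selection"))
  dist <- abs(post$pi_hat - model$target_toxicity)
  lvl <- max(which(dist <= min(dist) + 1e-12))
  structure(list(decision = "mtd", level = lvl, dose = model$dose_grid[lvl],
                 posterior = post),
            class = "mtd_selection")
}

#' @export
print.mtd_selection <- function(x, ...) {
  if (x$decision == "terminate") {
    cat("No MTD: early-termination rule fired on the final data\n")
  } else {
    cat(sprintf("MTD: dose level %d (%g mg/day), estimated toxicity %.3f\n",
                x$level, x$dose, x$posterior$pi_hat[x$level]))
  }
  invisible(x)
}
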