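#' Simulation scenario
#'
#' A true dose-toxicity state of nature for operating-characteristic
#' simulation: the per-dose DLT probabilities and the accrual limits.
#'
#' @param true_toxicity Per-dose true DLT probabilities in \[0, 1\].
#' @param max_patients Maximum evaluable patients (>= `cohort_size`).
#' @param cohort_size Patients per cohort.
#' @param seed Integer seed for the scenario's random draws.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(true_toxicity, max_patients = 18L,
                          cohort_size = 3L, seed = 1L) {
  true_toxicity <- as.numeric(true_toxicity)
  if (any(true_toxicity < 0) || any(true_toxicity > 1))
    stop("true_toxicity probabilities must lie in [0, 1]")
  if (max_patients < cohort_size)
    stop("max_patients must be at least cohort_size")
  structure(list(true_toxicity = true_toxicity,
                 max_patients = as.integer(max_patients),
                 cohort_size = as.integer(cohort_size),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# counter-based per-replicate seed derivation: independent, reproducible,
# and always below 2^31
.derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

#' Simulate one CRM trial
#'
#' Runs a full sequential trial under a true dose-toxicity scenario:
#' cohorts are assigned by [next_dose()], DLTs are drawn Bernoulli from the
#' scenario's true probabilities with the scenario seed, and the trial
#' stops at `max_patients` (partial final cohort allowed) or on early
#' termination. The same seed reproduces the trial exactly.
#'
#' @param model A [bma_crm_model()].
#' @param scenario A [scenario_spec()] whose `true_toxicity` has one entry
#'   per dose level.
#' @return A list with `trace` (an `"escalation_trace"` data frame built
#'   per cohort), `tally`, `outcome` (`"mtd"` or `"terminate"`),
#'   `mtd_level`, `mtd_dose`, `n_treated`, `n_dlt`.
#' @export
simulate_trial <- function(model, scenario) {
  stopifnot(inherits(model, "bma_crm_model"), inherits(scenario, "scenario_spec"))
  K <- length(model$dose_grid)
  if (length(scenario$true_toxicity) != K)
    stop("scenario true_toxicity must have one probability per dose level")
  set.seed(scenario$seed)
  n <- integer(K); y <- integer(K)
  level <- 1L; highest <- 0L
  treated <- 0L
  rows <- list()
  terminated <- FALSE
  while (treated < scenario$max_patients) {
    m <- min(scenario$cohort_size, scenario$max_patients - treated)
    dlts <- stats::rbinom(m, 1L, scenario$true_toxicity[level])
    n[level] <- n[level] + m
    y[level] <- y[level] + sum(dlts)
    treated <- treated + m
    highest <- max(highest, level)
    post <- bma_toxicity_estimates(model, toxicity_tally(n, y))
    rows[[length(rows) + 1L]] <- data.frame(
      order = length(rows) + 1L, n_used = treated,
      stats::setNames(as.data.frame(t(post$pi_hat)),
                      paste0("pi_hat_", seq_len(K))),
      p_overdose_lowest = post$p_lowest_overdose,
      assigned_level = level,
      decision = NA_character_)
    if (post$p_lowest_overdose > model$overdose_threshold) {
      terminated <- TRUE
      rows[[length(rows)]]$decision <- "terminate"
      break
    }
    nd <- next_dose(model, toxicity_tally(n, y), highest)
    if (nd$decision == "terminate") { terminated <- TRUE; break }
    level <- nd$level
    rows[[length(rows)]]$decision <- paste0("next:", level)
  }
  trace <- do.call(rbind, rows)
  class(trace) <- c("escalation_trace", "data.frame")
  tally <- toxicity_tally(n, y)
  if (terminated) {
    list(trace = trace, tally = tally, outcome = "terminate",
         mtd_level = NA_integer_, mtd_dose = NA_real_,
         n_treated = treated, n_dlt = sum(y))
  } else {
    sel <- select_mtd(model, tally)
    list(trace = trace, tally = tally, outcome = sel$decision,
         mtd_level = if (sel$decision == "mtd") sel$level else NA_integer_,
         mtd_dose = if (sel$decision == "mtd") sel$dose else NA_real_,
         n_treated = treated, n_dlt = sum(y))
  }
}

#' Operating characteristics under a scenario
#'
#' Aggregates independent simulated trials: how often each dose is selected
#' as MTD, how many patients are treated at each dose on average, the mean
#' DLT count, and the early-termination frequency. Replicate seeds are
#' derived from the scenario seed by a counter scheme, so each replicate is
#' individually reproducible and the whole summary is exact under a fixed
#' master seed.
#'
#' @inheritParams simulate_trial
#' @param n_sim Number of simulated trials (>= 1).
#' @return An object of class `"crm_oc"`: list with `selection_freq`
#'   (per dose), `termination_freq`, `mean_patients` (per dose),
#'   `mean_dlt`, `n_sim`.
#' @export
operating_characteristics <- function(model, scenario, n_sim = 1000L) {
  n_sim <- as.integer(n_sim)
  if (n_sim < 1L) stop("n_sim must be at least 1")
  K <- length(model$dose_grid)
  sel <- integer(K); term <- 0L
  pat <- numeric(K); dlt <- 0
  for (i in seq_len(n_sim)) {
    sc_i <- scenario
    sc_i$seed <- .derive_seed(scenario$seed, i)
    r <- simulate_trial(model, sc_i)
    if (r$outcome == "mtd") sel[r$mtd_level] <- sel[r$mtd_level] + 1L
    else term <- term + 1L
    pat <- pat + r$tally$n
    dlt <- dlt + r$n_dlt
  }
  structure(list(selection_freq = sel / n_sim,
                 termination_freq = term / n_sim,
                 mean_patients = pat / n_sim,
                 mean_dlt = dlt / n_sim,
                 n_sim = n_sim),
            class = "crm_oc")
}

#' @export
print.crm_oc <- function(x, ...) {
  cat("Operating characteristics over", x$n_sim, "simulated trials\n")
  cat("  MTD selection freq:", paste(sprintf("%.3f", x$selection_freq),
                                     collapse = ", "), "\n")
  cat("  early termination: ", sprintf("%.3f", x$termination_freq), "\n")
  cat("  mean patients/dose:", paste(sprintf("%.2f", x$mean_patients),
                                     collapse = ", "), "\n")
  cat("  mean DLT count:    ", sprintf("%.2f", x$mean_dlt), "\n")
  invisible(x)
}
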