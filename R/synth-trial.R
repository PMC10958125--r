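#' Generate Bernoulli DLT outcomes for fixed assignments
#'
#' Draws independent DLT flags for a sequence of dose assignments under a
#' scenario's true per-dose toxicity probabilities.
#'
#' @param scenario A [scenario_spec()].
#' @param assignments Integer vector of dose levels, one per patient.
#' @param seed Integer seed (defaults to the scenario seed).
#' @return A [patient_records()] data frame, all patients evaluable.
#' @export
generate_dlt_outcomes <- function(scenario, assignments,
                                  seed = scenario$seed) {
  stopifnot(inherits(scenario, "scenario_spec"))
  assignments <- as.integer(assignments)
  if (any(assignments < 1L) ||
      any(assignments > length(scenario$true_toxicity)))
    stop("assignments must index the scenario's dose levels")
  set.seed(seed)
  dlt <- stats::rbinom(length(assignments), 1L,
                       scenario$true_toxicity[assignments])
  patient_records(data.frame(
    patient_id = seq_along(assignments),
    enrollment_order = seq_along(assignments),
    dose_level = assignments,
    dlt = as.logical(dlt),
    evaluable = TRUE), n_levels = length(scenario$true_toxicity))
}

#' Generate a complete end-to-end trial dataset
#'
#' One call produces every input the analysis pipeline consumes, all
#' derived from a single master seed: the reconstructed escalation
#' enrollment record (see [study_enrollment()]), the default BMA-CRM model
#' configuration, paired PK profiles for the PK cohort, and the correlative
#' biomarker panel. When `dir` is given, the bundle is also written as the
#' delimited-text/JSON dialects the package readers accept.
#'
#' @param master_seed Integer master seed.
#' @param dir Optional output directory (created if missing).
#' @param pk_params,biomarker_params Optional simulator parameter overrides.
#' @return A list: `model`, `trial_records`, `pk_profiles`, `pk_table`,
#'   `biomarker_panel`, and (when written) `paths`.
#' @export
generate_trial_dataset <- function(master_seed = 1L, dir = NULL,
                                   pk_params = pk_sim_params(),
                                   biomarker_params = biomarker_sim_params()) {
  model <- bma_crm_model()
  records <- study_enrollment()
  profiles <- generate_pk_profiles(pk_params,
                                   seed = .derive_seed(master_seed, 101L))
  panel <- generate_biomarker_panel(biomarker_params,
                                    seed = .derive_seed(master_seed, 202L))
  out <- list(model = model, trial_records = records,
              pk_profiles = profiles,
              pk_table = pk_profiles_to_table(profiles),
              biomarker_panel = panel)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      model = file.path(dir, "model.json"),
      trial = file.path(dir, "trial_records.csv"),
      pk = file.path(dir, "pk_concentrations.csv"),
      biomarkers = file.path(dir, "biomarkers.csv"),
      phospho = file.path(dir, "phospho_assay.csv"),
      psa = file.path(dir, "psa.csv"))
    write_model_config(model, paths[["model"]])
    write_trial_records(records, paths[["trial"]])
    utils::write.csv(out$pk_table, paths[["pk"]], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(panel$biomarkers, paths[["biomarkers"]],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(panel$phospho, paths[["phospho"]], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(panel$psa, paths[["psa"]], row.names = FALSE,
                     quote = FALSE)
    out$paths <- paths
  }
  out
}
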