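test_that("replay of the reconstructed enrollment regenerates the trace", {
  m <- default_model()
  tr <- replay_trial(m, study_enrollment())
  # one row per evaluable patient (17) plus the final full-data row
  expect_identical(nrow(tr), 18L)
  expect_true(all(diff(tr$n_used) >= 0))
  expect_identical(tr$n_used[1], 0L)
  expect_identical(tr$n_used[18], 17L)
  # the withdrawn patient contributes nothing and has no row
  expect_false(13L %in% tr$patient_id)
  # prior row is the equal-weight skeleton average
  expect_equal(unlist(tr[1, c("pi_hat_1", "pi_hat_2", "pi_hat_3")]),
               c(pi_hat_1 = 0.065, pi_hat_2 = 0.15, pi_hat_3 = 0.3),
               tolerance = 1e-9)
  # the DLT (13th evaluable patient) produces the jump in the next row
  expect_gt(tr$pi_hat_3[tr$n_used == 13], tr$pi_hat_3[tr$n_used == 12])
  # assignments never skip a level (one-step escalation audit)
  lev <- tr$assigned_level[!is.na(tr$assigned_level)]
  expect_true(all(diff(cummax(lev)) <= 1))
  # final row agrees with a direct computation on the final tally
  final <- bma_toxicity_estimates(m, toxicity_tally(c(3, 3, 11), c(0, 0, 1)))
  expect_equal(unlist(tr[18, c("pi_hat_1", "pi_hat_2", "pi_hat_3")],
                      use.names = FALSE),
               final$pi_hat, tolerance = 1e-10)
})

test_that("replay handles empty records and is tally-sufficient", {
  m <- default_model()
  empty_rec <- patient_records(data.frame(
    patient_id = integer(), enrollment_order = integer(),
    dose_level = integer(), dlt = logical(), evaluable = logical()))
  tr0 <- replay_trial(m, empty_rec)
  expect_identical(nrow(tr0), 1L)
  expect_equal(unlist(tr0[1, c("pi_hat_1", "pi_hat_2", "pi_hat_3")],
                      use.names = FALSE),
               c(0.065, 0.15, 0.3), tolerance = 1e-9)
  # swapping two same-dose patients within a cohort changes nothing downstream
  rec <- study_enrollment()
  swapped <- rec
  swapped[1:2, c("patient_id", "dlt", "evaluable")] <-
    rec[2:1, c("patient_id", "dlt", "evaluable")]
  tr_a <- replay_trial(m, rec)
  tr_b <- replay_trial(m, patient_records(as.data.frame(swapped)))
  expect_equal(tr_a$pi_hat_3[3:18], tr_b$pi_hat_3[3:18], tolerance = 1e-12)
})

test_that("per-cohort cadence repeats estimates within cohorts", {
  m <- default_model()
  tr <- replay_trial(m, study_enrollment(), cadence = "per-cohort")
  # rows 2 and 3 (within cohort 1) reuse the estimates in force at opening
  expect_identical(tr$pi_hat_3[2], tr$pi_hat_3[1])
  expect_identical(tr$pi_hat_3[3], tr$pi_hat_3[1])
  # cohort boundary rows refresh
  expect_false(tr$pi_hat_3[4] == tr$pi_hat_3[3])
})

test_that("degenerate scenarios force the expected simulated outcomes", {
  m <- default_model()
  # no toxicity anywhere: no DLTs, escalate, MTD = highest dose
  s0 <- simulate_trial(m, scenario_spec(c(0, 0, 0), seed = 11L))
  expect_identical(s0$outcome, "mtd")
  expect_identical(s0$mtd_dose, 150)
  expect_identical(s0$n_dlt, 0L)
  # certain toxicity: DLT count equals patients treated, early termination
  s1 <- simulate_trial(m, scenario_spec(c(1, 1, 1), seed = 11L))
  expect_identical(s1$outcome, "terminate")
  expect_identical(s1$n_dlt, s1$n_treated)
  # determinism: same seed, identical trace
  s2 <- simulate_trial(m, scenario_spec(c(0.1, 0.25, 0.5), seed = 99L))
  s3 <- simulate_trial(m, scenario_spec(c(0.1, 0.25, 0.5), seed = 99L))
  expect_identical(s2$trace, s3$trace)
  # no-skipping audit on a stochastic run
  lev <- s2$trace$assigned_level
  expect_true(all(diff(cummax(lev)) <= 1))
})

test_that("operating characteristics aggregate and reproduce exactly", {
  m <- default_model()
  sc <- scenario_spec(c(0, 0, 0), seed = 5L)
  oc <- operating_characteristics(m, sc, n_sim = 5L)
  expect_identical(oc$selection_freq[3], 1)
  expect_identical(oc$termination_freq, 0)
  expect_identical(oc$mean_dlt, 0)
  expect_lte(sum(oc$mean_patients), sc$max_patients)
  # frequencies live on the 1/n_sim grid and sum to 1 with termination
  oc1 <- operating_characteristics(m, scenario_spec(c(0.3, 0.5, 0.7),
                                                    seed = 3L), n_sim = 1L)
  expect_true(all(c(oc1$selection_freq, oc1$termination_freq) %in% c(0, 1)))
  expect_equal(sum(oc1$selection_freq) + oc1$termination_freq, 1)
  # exact reproducibility under the master seed
  oc_a <- operating_characteristics(m, scenario_spec(c(0.05, 0.2, 0.4),
                                                     seed = 17L), n_sim = 8L)
  oc_b <- operating_characteristics(m, scenario_spec(c(0.05, 0.2, 0.4),
                                                     seed = 17L), n_sim = 8L)
  expect_identical(oc_a, oc_b)
})

test_that("trial records round-trip through CSV and bad files are named", {
  rec <- study_enrollment()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_records(rec, path)
  back <- read_trial_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  # out-of-grid dose reports the offending line
  bad <- as.data.frame(rec)
  bad$dose_level[5] <- 4L
  utils::write.csv(transform(bad, dlt = as.integer(dlt),
                             evaluable = as.integer(evaluable)),
                   path, row.names = FALSE)
  expect_error(read_trial_records(path), "line 6")
  # missing column is fatal
  utils::write.csv(bad[, -3], path, row.names = FALSE)
  expect_error(read_trial_records(path), "dose_level")
  # trace writer produces a readable CSV
  tr <- replay_trial(default_model(), rec)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, tpath)
  expect_equal(nrow(utils::read.csv(tpath)), nrow(tr))
})
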