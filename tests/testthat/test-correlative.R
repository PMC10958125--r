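test_that("baseline fold change normalises to day 1", {
  expect_equal(fold_change(c(788, 1576), c(1, 57)), c(1, 2))
  expect_equal(fold_change(rep(42, 6), c(1, 15, 36, 57, 78, 99)), rep(1, 6))
  # idempotence on positive series
  set.seed(3)
  v <- rlnorm(6); d <- c(1, 15, 36, 57, 78, 99)
  expect_equal(fold_change(fold_change(v, d), d), fold_change(v, d),
               tolerance = 1e-12)
  expect_error(fold_change(c(0, 2), c(1, 15)), "positive")
  expect_error(fold_change(c(5, 2), c(15, 36)), "baseline")
})

test_that("phosphorylation ratio is a scale-invariant stimulated/unstimulated quotient", {
  expect_equal(ligand_dependent_phosphorylation(10.9, 1), 10.9)
  expect_equal(ligand_dependent_phosphorylation(7, 7), 1)
  expect_equal(ligand_dependent_phosphorylation(2 * 6.2, 2 * 1.3),
               ligand_dependent_phosphorylation(6.2, 1.3), tolerance = 1e-12)
  expect_error(ligand_dependent_phosphorylation(-1, 2), "positive")
})

test_that("exact Wilcoxon equals full enumeration for n <= 10", {
  # extreme configuration: all five differences negative
  res <- wilcoxon_signed_rank_exact(c(-3, -1, -4, -2, -5), "less")
  expect_identical(res$statistic, 0)
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$exact)
  # randomized suites, with and without ties, against brute enumeration
  set.seed(77)
  for (n in 2:10) {
    for (rep in 1:6) {
      d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties guaranteed often
      for (alt in c("less", "greater", "two.sided")) {
        expect_equal(wilcoxon_signed_rank_exact(d, alt)$p_value,
                     oracle_wilcoxon(d, alt),
                     tolerance = 1e-12, label = paste("n", n, alt))
      }
    }
  }
  # tie-free case agrees with stats::wilcox.test exact p
  d <- c(2.3, -1.1, 0.7, -3.2, 4.4, -0.2, 1.9)
  expect_equal(wilcoxon_signed_rank_exact(d, "greater")$p_value,
               wilcox.test(d, alternative = "greater", exact = TRUE)$p.value,
               tolerance = 1e-12)
  # sign symmetry with mirrored alternative
  expect_equal(wilcoxon_signed_rank_exact(d, "greater")$p_value,
               wilcoxon_signed_rank_exact(-d, "less")$p_value,
               tolerance = 1e-12)
  # zeros are dropped; all-zero input is flagged
  expect_identical(wilcoxon_signed_rank_exact(c(0, -1, 2), "less")$n, 2L)
  expect_warning(res0 <- wilcoxon_signed_rank_exact(c(0, 0)), "zero")
  expect_true(is.na(res0$p_value))
  # p always in (0, 1]
  set.seed(8)
  for (rep in 1:20) {
    d <- rnorm(sample(3:12, 1))
    p <- wilcoxon_signed_rank_exact(d, sample(c("less", "greater",
                                                "two.sided"), 1))$p_value
    expect_true(p > 0 && p <= 1)
  }
})

test_that("large-sample Wilcoxon approximation tracks the normal tail", {
  set.seed(5)
  d <- rnorm(40, -0.5)
  res <- wilcoxon_signed_rank_exact(d, "less")
  expect_false(res$exact)
  ref <- wilcox.test(d, alternative = "less", exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-10)
})

test_that("one-sided paired t matches the textbook formula and t.test", {
  set.seed(21)
  x <- rnorm(8, 10); y <- rnorm(8, 10.8)
  res <- paired_t_one_sided(x, y, "greater")
  d <- y - x
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, pt(t_manual, 7, lower.tail = FALSE),
               tolerance = 1e-12)
  ref <- t.test(y, x, paired = TRUE, alternative = "greater")
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # x = y gives t = 0... but zero variance is flagged instead
  expect_warning(res0 <- paired_t_one_sided(x, x, "greater"), "variance")
  expect_true(is.na(res0$t))
  # equal-mean null: identical-difference shift with noise
  res_shift <- paired_t_one_sided(x, x + rnorm(8, 0, 1e-8) + 1, "greater")
  expect_lt(res_shift$p_value, 1e-6)
})

test_that("PSA response uses the nadir with an inclusive -50% boundary", {
  r <- psa_response(100, c(80, 27.19, 35))
  expect_equal(r$percent_change, -72.81)
  expect_true(r$responder)
  expect_true(psa_response(100, 50)$responder)       # boundary inclusive
  expect_false(psa_response(100, 51)$responder)
  rising <- psa_response(10, c(12, 15))
  expect_gt(rising$percent_change, 0)
  expect_false(rising$responder)
  # monotone: lowering a follow-up can never destroy responder status
  set.seed(9)
  for (rep in 1:25) {
    base <- runif(1, 5, 200)
    fu <- runif(4, 0.1 * base, 1.5 * base)
    r1 <- psa_response(base, fu)
    fu2 <- fu; i <- sample(4, 1); fu2[i] <- fu2[i] * runif(1)
    r2 <- psa_response(base, fu2)
    expect_true(!r1$responder || r2$responder)
  }
  expect_error(psa_response(0, 5), "positive")
  expect_error(psa_response(10, numeric()), "follow-up")
})

test_that("biomarker tables read and fold-change end to end", {
  panel <- generate_biomarker_panel(biomarker_sim_params(), seed = 6L)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(panel$biomarkers, path, row.names = FALSE)
  bm <- read_biomarker_data(path)
  expect_identical(names(bm), c("subject", "dose_group", "analyte", "day",
                                "value"))
  fc <- biomarker_fold_changes(bm)
  expect_true(all(abs(fc$fold_change[fc$day == 1] - 1) < 1e-12))
  # phospho table read through the stimulated/unstimulated route
  ph <- panel$phospho
  ph$analyte <- "pigf1r_ratio"
  utils::write.csv(ph, path, row.names = FALSE)
  bm2 <- read_biomarker_data(path)
  expect_equal(bm2$value,
               ph[order(ph$subject, ph$day), "stimulated"] /
                 ph[order(ph$subject, ph$day), "unstimulated"],
               tolerance = 1e-12)
})
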