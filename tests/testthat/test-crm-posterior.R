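sk1 <- skeleton(c(0.05, 0.1, 0.2))
sk2 <- skeleton(c(0.08, 0.2, 0.4))
empty <- toxicity_tally(c(0, 0, 0), c(0, 0, 0))

test_that("log likelihood matches direct evaluation", {
  # empty tally: empty product
  expect_identical(crm_log_likelihood(0.7, sk1, empty), 0)
  # single non-DLT at dose 1, alpha = 0
  expect_equal(crm_log_likelihood(0, sk1, toxicity_tally(c(1, 0, 0), c(0, 0, 0))),
               log(0.95), tolerance = 1e-12)
  # general case against the direct-product oracle (frozen value)
  t337 <- toxicity_tally(c(3, 3, 7), c(0, 0, 1))
  expect_equal(crm_log_likelihood(0.3, sk2, t337), -3.7578927746,
               tolerance = 1e-9)
  # vectorised over alpha, agrees with the oracle pointwise
  a <- c(-2, -0.5, 0, 0.8, 3)
  expect_equal(crm_log_likelihood(a, sk2, t337),
               vapply(a, oracle_loglik, 0, sk = unclass(sk2),
                      n = t337$n, y = t337$y),
               tolerance = 1e-12)
})

test_that("posterior mean and marginal agree with adaptive-integration oracle", {
  t1 <- toxicity_tally(c(1, 0, 0), c(0, 0, 0))
  # frozen oracle values (stats::integrate, rel.tol 1e-11)
  expect_equal(posterior_alpha_mean(sk1, t1, sqrt(2)), 0.3822135074,
               tolerance = 1e-7)
  expect_equal(posterior_alpha_mean(sk1, t1, 1 / sqrt(2)), 0.0920843655,
               tolerance = 1e-7)
  expect_equal(log_marginal_likelihood(sk1, t1, sqrt(2)), -0.2075907830,
               tolerance = 1e-7)
  # empty data: symmetric prior, flat likelihood
  expect_equal(posterior_alpha_mean(sk1, empty), 0, tolerance = 1e-10)
  expect_equal(log_marginal_likelihood(sk1, empty), 0, tolerance = 1e-10)
  # a heavier tally, oracle recomputed in place
  t2 <- toxicity_tally(c(3, 3, 7), c(0, 0, 2))
  expect_equal(posterior_alpha_mean(sk2, t2, 1 / sqrt(2)),
               oracle_alpha_mean(unclass(sk2), t2$n, t2$y, 1 / sqrt(2)),
               tolerance = 1e-7)
})

test_that("posterior mean agrees with a Monte-Carlo sampling estimate", {
  t1 <- toxicity_tally(c(2, 3, 1), c(0, 1, 0))
  set.seed(42)
  a <- rnorm(4e5, 0, sqrt(2))
  w <- exp(vapply(a, oracle_loglik, 0, sk = unclass(sk1), n = t1$n, y = t1$y))
  mc <- sum(a * w) / sum(w)
  mc_se <- sqrt(sum(w^2 * (a - mc)^2) / sum(w)^2)
  expect_lt(abs(posterior_alpha_mean(sk1, t1, sqrt(2)) - mc), 3 * mc_se)
})

test_that("model weights behave as posterior model probabilities", {
  m <- default_model()
  # no data, uniform prior: equal marginals
  expect_equal(model_weights(m, empty), c(0.5, 0.5), tolerance = 1e-12)
  # identical skeletons: symmetry for any tally
  m_same <- bma_crm_model(skeletons = list(sk1, sk1))
  t1 <- toxicity_tally(c(3, 2, 1), c(1, 0, 0))
  expect_equal(model_weights(m_same, t1), c(0.5, 0.5), tolerance = 1e-12)
  # a DLT at dose 3 favours the steeper skeleton; frozen oracle values
  t_dlt3 <- toxicity_tally(c(0, 0, 1), c(0, 0, 1))
  expect_equal(model_weights(m, t_dlt3), c(0.3739187684, 0.6260812316),
               tolerance = 1e-7)
})

test_that("prior estimates and single-skeleton identity hold", {
  m <- default_model()
  expect_equal(bma_toxicity_estimates(m, empty)$pi_hat, c(0.065, 0.15, 0.3),
               tolerance = 1e-9)
  m1 <- bma_crm_model(skeletons = list(sk1))
  expect_equal(bma_toxicity_estimates(m1, empty)$pi_hat, c(0.05, 0.1, 0.2),
               tolerance = 1e-9)
})

test_that("overdose probability matches closed form and sampling oracle", {
  # single skeleton, no data: Phi(log(log target / log p1) / sd)
  for (s in c(1 / sqrt(2), sqrt(2))) {
    m1 <- bma_crm_model(skeletons = list(sk1), alpha_prior_sd = s)
    expect_equal(overdose_probability_lowest_dose(m1, empty),
                 pnorm(log(log(0.2) / log(0.05)) / s), tolerance = 1e-5)
  }
  # target = 1: the probability of exceeding 1 is zero
  m_t1 <- bma_crm_model(target_toxicity = 0.999999)
  expect_lt(overdose_probability_lowest_dose(m_t1, empty), 1e-4)
  # extreme toxicity at dose 1: termination regime (oracle value 0.99844)
  t66 <- toxicity_tally(c(6, 0, 0), c(6, 0, 0))
  m <- default_model()
  expect_equal(overdose_probability_lowest_dose(m, t66), 0.99843708,
               tolerance = 1e-5)
  expect_true(should_terminate(m, t66))
  # default prior overdose probability is below the threshold (frozen 0.22588)
  expect_equal(overdose_probability_lowest_dose(m, empty), 0.22587805,
               tolerance = 1e-5)
  expect_false(should_terminate(m, empty))
  # data-bearing case against the adaptive-integration oracle
  t1 <- toxicity_tally(c(3, 1, 0), c(1, 1, 0))
  m1 <- bma_crm_model(skeletons = list(sk1))
  expect_equal(overdose_probability_lowest_dose(m1, t1),
               oracle_overdose(unclass(sk1), t1$n, t1$y, 1 / sqrt(2)),
               tolerance = 1e-6)
})

test_that("quadrature is converged: doubling nodes moves nothing by 1e-6", {
  t1 <- toxicity_tally(c(3, 3, 7), c(0, 0, 1))
  m_a <- default_model()
  m_b <- default_model(quadrature = quad_spec(nodes = 2L * 4097L - 1L))
  pa <- bma_toxicity_estimates(m_a, t1)
  pb <- bma_toxicity_estimates(m_b, t1)
  expect_lt(max(abs(pa$pi_hat - pb$pi_hat)), 1e-6)
  expect_lt(max(abs(pa$alpha_hat - pb$alpha_hat)), 1e-6)
  expect_lt(max(abs(pa$log_marginal - pb$log_marginal)), 1e-6)
  expect_lt(abs(pa$p_lowest_overdose - pb$p_lowest_overdose), 1e-6)
})

test_that("randomized tallies: weights sum to 1, pi_hat monotone, DLTs move estimates the right way", {
  m <- default_model()
  set.seed(2024)
  for (rep in 1:120) {
    n <- sample(0:6, 3, replace = TRUE)
    y <- vapply(n, function(nn) sample(0:nn, 1), 0L)
    tl <- toxicity_tally(n, y)
    post <- bma_toxicity_estimates(m, tl)
    expect_lt(abs(sum(post$model_weights) - 1), 1e-10)
    expect_true(all(post$model_weights >= 0 & post$model_weights <= 1))
    expect_true(all(post$pi_hat > 0 & post$pi_hat < 1))
    expect_true(all(diff(post$pi_hat) > 0))
    expect_true(post$p_lowest_overdose >= 0 && post$p_lowest_overdose <= 1)
    # add one DLT at a random dose: no estimate may decrease
    j <- sample(1:3, 1)
    n2 <- n; y2 <- y; n2[j] <- n2[j] + 1L; y2[j] <- y2[j] + 1L
    post_up <- bma_toxicity_estimates(m, toxicity_tally(n2, y2))
    expect_true(all(post_up$pi_hat >= post$pi_hat - 1e-9))
    # add one non-DLT: no estimate may increase
    n3 <- n; n3[j] <- n3[j] + 1L
    post_dn <- bma_toxicity_estimates(m, toxicity_tally(n3, y))
    expect_true(all(post_dn$pi_hat <= post$pi_hat + 1e-9))
  }
})

test_that("estimator variants are ordered sensibly and exposed", {
  t1 <- toxicity_tally(c(3, 3, 0), c(0, 0, 0))
  plugin <- bma_toxicity_estimates(default_model(), t1)$pi_hat
  pimean <- bma_toxicity_estimates(default_model(estimator = "pi_mean"), t1)$pi_hat
  mode_ <- bma_toxicity_estimates(default_model(estimator = "plugin_mode"), t1)$pi_hat
  # with only non-DLT data the posterior-mean-of-pi estimate exceeds the
  # plug-in (Jensen: p^exp(alpha) is convex in alpha on this range)
  expect_true(all(pimean > plugin))
  expect_true(all(mode_ > 0 & mode_ < 1))
})
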