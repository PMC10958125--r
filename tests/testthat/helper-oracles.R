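# Independent oracles used across the CRM tests. These deliberately avoid
# the package's quadrature path: direct likelihood evaluation plus adaptive
# integration via stats::integrate over the whole real line.

oracle_loglik <- function(alpha, sk, n, y) {
  s <- 0
  for (j in seq_along(sk)) {
    p <- sk[j]^exp(alpha)
    if (y[j] > 0) s <- s + y[j] * log(p)
    if (n[j] - y[j] > 0) s <- s + (n[j] - y[j]) * log1p(-p)
  }
  s
}

.oracle_int <- function(f, sk, n, y, sd, lower = -Inf, upper = Inf) {
  stats::integrate(function(a)
    vapply(a, function(ai) f(ai) * exp(oracle_loglik(ai, sk, n, y)), 0) *
      stats::dnorm(a, 0, sd),
    lower, upper, rel.tol = 1e-11)$value
}

oracle_marginal <- function(sk, n, y, sd)
  .oracle_int(function(a) 1, sk, n, y, sd)

oracle_alpha_mean <- function(sk, n, y, sd)
  .oracle_int(function(a) a, sk, n, y, sd) / oracle_marginal(sk, n, y, sd)

oracle_overdose <- function(sk, n, y, sd, target = 0.2) {
  astar <- log(log(target) / log(sk[1]))
  .oracle_int(function(a) 1, sk, n, y, sd, upper = astar) /
    oracle_marginal(sk, n, y, sd)
}

# brute-force exact signed-rank tail: enumerate every sign assignment
oracle_wilcoxon <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, 0)
  switch(alternative,
         less = mean(vs <= v_obs + 1e-9),
         greater = mean(vs >= v_obs - 1e-9),
         two.sided = min(1, 2 * min(mean(vs <= v_obs + 1e-9),
                                    mean(vs >= v_obs - 1e-9))))
}

default_model <- function(...) bma_crm_model(...)
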