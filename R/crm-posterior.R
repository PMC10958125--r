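#' Binomial CRM log likelihood
#'
#' Log likelihood of the working model `pi_j = p_j^exp(alpha)` for a
#' per-dose toxicity tally: the product over dose levels of
#' `pi_j^y_j (1 - pi_j)^(n_j - y_j)`. An empty tally gives 0.
#'
#' @param alpha Model parameter (scalar or vector; vectorised over `alpha`).
#' @param skeleton A [skeleton()] (or numeric vector accepted by it).
#' @param tally A [toxicity_tally()].
#' @return Log likelihood value(s), finite for finite `alpha` (may be
#'   `-Inf` at extreme `alpha` when the data contain non-DLTs).
#' @export
crm_log_likelihood <- function(alpha, skeleton, tally) {
  if (!inherits(skeleton, "skeleton")) skeleton <- skeleton(skeleton)
  stopifnot(inherits(tally, "toxicity_tally"))
  if (length(tally$n) != length(skeleton))
    stop("tally and skeleton must cover the same dose levels")
  out <- numeric(length(alpha))
  e <- exp(alpha)
  for (j in seq_along(skeleton)) {
    lp <- e * log(skeleton[[j]])       # log pi_j, always < 0
    if (tally$y[j] > 0)
      out <- out + tally$y[j] * lp
    if (tally$n[j] - tally$y[j] > 0)
      out <- out + (tally$n[j] - tally$y[j]) * log1p(-exp(lp))
  }
  out
}

# Shared grid posterior for one skeleton: returns nodes, log prior+lik,
# normalised density, log marginal, posterior mean/mode of alpha.
# Deterministic trapezoidal quadrature in log space (no sampling noise).
.alpha_posterior <- function(skeleton, tally, prior_sd, quad) {
  a <- seq(-quad$bound_sd * prior_sd, quad$bound_sd * prior_sd,
           length.out = quad$nodes)
  h <- a[2L] - a[1L]
  lf <- crm_log_likelihood(a, skeleton, tally) +
    stats::dnorm(a, 0, prior_sd, log = TRUE)
  if (all(!is.finite(lf)))
    stop("quadrature failure: log posterior is -Inf over the whole grid ",
         "(bound_sd = ", quad$bound_sd, ", nodes = ", quad$nodes, ")")
  m <- max(lf)
  f <- exp(lf - m)
  trap <- function(g) sum((g[-1L] + g[-length(g)]) / 2) * h
  mass <- trap(f)
  if (!is.finite(mass) || mass <= 0)
    stop("quadrature failure: zero or non-finite posterior mass")
  list(a = a, h = h, dens = f / mass, trap = trap,
       log_marginal = log(mass) + m,
       mean = trap(a * f) / mass,
       mode = a[which.max(lf)])
}

#' Posterior mean of the model parameter for one skeleton
#'
#' Posterior mean of `alpha` under the zero-mean normal prior and the
#' binomial CRM likelihood, by deterministic fixed-grid quadrature. With an
#' empty tally the likelihood is flat and the symmetric prior gives 0.
#'
#' @inheritParams crm_log_likelihood
#' @param prior_sd Prior standard deviation of `alpha`.
#' @param quad A [quad_spec()].
#' @return Scalar posterior mean.
#' @export
posterior_alpha_mean <- function(skeleton, tally, prior_sd = 1 / sqrt(2),
                                 quad = quad_spec()) {
  .alpha_posterior(skeleton, tally, prior_sd, quad)$mean
}

#' Log marginal likelihood for one skeleton
#'
#' `log integral of likelihood(alpha) * prior(alpha) d alpha`; the
#' model-evidence term that drives the Bayesian model-averaging weights.
#' Equals 0 for an empty tally (the likelihood is identically 1).
#'
#' @inheritParams posterior_alpha_mean
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(skeleton, tally, prior_sd = 1 / sqrt(2),
                                    quad = quad_spec()) {
  .alpha_posterior(skeleton, tally, prior_sd, quad)$log_marginal
}

#' Posterior model weights
#'
#' Posterior probability of each skeleton:
#' `w_k` proportional to `prior_model_probs_k * exp(log marginal_k)`,
#' combined in log space to avoid underflow.
#'
#' @param model A [bma_crm_model()].
#' @param tally A [toxicity_tally()].
#' @return Numeric vector of weights summing to 1.
#' @export
model_weights <- function(model, tally) {
  stopifnot(inherits(model, "bma_crm_model"))
  lm <- vapply(model$skeletons, function(s)
    log_marginal_likelihood(s, tally, model$alpha_prior_sd, model$quadrature),
    0)
  lw <- log(model$prior_model_probs) + lm
  lw <- lw - max(lw[is.finite(lw)])
  w <- exp(lw)
  if (!any(is.finite(w)) || sum(w) == 0)
    stop("model weights underflowed; check the tally and quadrature settings")
  w / sum(w)
}

#' Model-averaged posterior summary
#'
#' Runs the per-skeleton posterior computations and combines them into the
#' quantities the design acts on: per-model `alpha` estimates and log
#' marginal likelihoods, posterior model weights, model-averaged per-dose
#' toxicity estimates, and the posterior probability that the lowest dose
#' is more toxic than the target.
#'
#' With the default `"plugin"` estimator the per-dose estimate is
#' `sum_k w_k * p_(k,j)^exp(alpha_hat_k)` with `alpha_hat_k` the posterior
#' mean of `alpha` under model `k`; `"plugin_mode"` replaces the mean by the
#' mode, and `"pi_mean"` uses the full posterior mean of `p^exp(alpha)`.
#'
#' @inheritParams model_weights
#' @return An object of class `"crm_posterior"`: a list with `alpha_hat`,
#'   `log_marginal`, `model_weights`, `pi_hat`, `p_lowest_overdose`,
#'   `estimator`, `target`.
#' @examples
#' m <- bma_crm_model()
#' bma_toxicity_estimates(m, toxicity_tally(c(0, 0, 0), c(0, 0, 0)))$pi_hat
#' @export
bma_toxicity_estimates <- function(model, tally) {
  stopifnot(inherits(model, "bma_crm_model"), inherits(tally, "toxicity_tally"))
  K <- length(model$skeletons)
  posts <- lapply(model$skeletons, .alpha_posterior, tally = tally,
                  prior_sd = model$alpha_prior_sd, quad = model$quadrature)
  lm <- vapply(posts, `[[`, 0, "log_marginal")
  lw <- log(model$prior_model_probs) + lm
  lw <- lw - max(lw)
  w <- exp(lw) / sum(exp(lw))

  pi_k <- matrix(NA_real_, K, length(model$dose_grid))
  alpha_hat <- numeric(K)
  for (k in seq_len(K)) {
    p <- posts[[k]]
    sk <- unclass(model$skeletons[[k]])
    alpha_hat[k] <- switch(model$estimator,
                           plugin = p$mean,
                           plugin_mode = p$mode,
                           pi_mean = p$mean)
    pi_k[k, ] <- switch(model$estimator,
      plugin      = sk^exp(p$mean),
      plugin_mode = sk^exp(p$mode),
      pi_mean     = vapply(sk, function(s) p$trap(s^exp(p$a) * p$dens), 0))
  }
  pi_hat <- as.numeric(w %*% pi_k)

  p_over <- sum(w * vapply(seq_len(K), function(k)
    .overdose_prob_one(posts[[k]], model$skeletons[[k]][[1L]],
                       model$target_toxicity), 0))

  structure(list(alpha_hat = alpha_hat, log_marginal = lm, model_weights = w,
                 pi_hat = pi_hat, p_lowest_overdose = p_over,
                 estimator = model$estimator, target = model$target_toxicity),
            class = "crm_posterior")
}

# Pr(p1^exp(alpha) > target | data, model k) = Pr(alpha < a*) with
# a* = log(log(target) / log(p1)); both logs negative so the power model
# exceeds the target exactly when exp(alpha) < log(target)/log(p1).
.overdose_prob_one <- function(post, p1, target) {
  if (target >= 1) return(0)
  if (target <= 0) return(1)
  astar <- log(log(target) / log(p1))
  a <- post$a; d <- post$dens; h <- post$h
  if (astar <= a[1L]) return(0)
  if (astar >= a[length(a)]) return(1)
  i <- findInterval(astar, a)             # a[i] <= astar < a[i+1]
  cum <- if (i > 1L) sum((d[1:(i - 1L)] + d[2:i]) / 2) * h else 0
  # partial trapezoid from a[i] to astar with linear density interpolation
  frac <- (astar - a[i]) / h
  d_at <- d[i] + frac * (d[i + 1L] - d[i])
  min(1, max(0, cum + (d[i] + d_at) / 2 * (astar - a[i])))
}

#' Posterior probability that the lowest dose exceeds the target
#'
#' `Pr(pi_1 > target | data)`: the model-averaged posterior probability
#' that the toxicity probability at dose level 1 exceeds the target rate.
#' This is the quantity the early-termination rule thresholds.
#'
#' @inheritParams model_weights
#' @return Probability in \[0, 1\].
#' @export
overdose_probability_lowest_dose <- function(model, tally) {
  bma_toxicity_estimates(model, tally)$p_lowest_overdose
}

#' @export
print.crm_posterior <- function(x, ...) {
  cat("BMA-CRM posterior (", x$estimator, " estimator)\n", sep = "")
  cat("  model weights:", paste(sprintf("%.3f", x$model_weights),
                                collapse = ", "), "\n")
  cat("  pi_hat:", paste(sprintf("%.3f", x$pi_hat), collapse = ", "), "\n")
  cat(sprintf("  Pr(pi_1 > %.2g | data) = %.3f\n", x$target,
              x$p_lowest_overdose))
  invisible(x)
}
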