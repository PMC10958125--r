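---
title: "Methods: BMA-CRM dose finding, docetaxel NCA and correlative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BMA-CRM dose finding, docetaxel NCA and correlative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lycodose)
```

This vignette is the package's account of its own methods: the
dose-finding model and the choices made where the trial's public record
leaves the computation under-determined, the non-compartmental
pharmacokinetic (PK) conventions, the small-sample correlative tests, and
what the synthetic-data generators do and do not emulate.

## The dose-finding model

A phase I design treats dose levels `1..K` (30, 90, 150 mg/day of
lycopene on top of fixed-dose docetaxel) and observes a binary
dose-limiting toxicity (DLT) for each evaluable patient, adjudicated over
the days 1–36 window upstream of this package — the engine sees only
already-adjudicated flags, not times to event. The sufficient statistic is
the per-dose tally `(n_j, y_j)` of evaluable patients and DLTs; all
posterior quantities are invariant to patient order within a tally.

Each candidate skeleton `p_(k,j)` (two here: `.05/.1/.2` and `.08/.2/.4`,
equal prior weight) defines a one-parameter working model
`pi_(k,j) = p_(k,j)^exp(alpha)` with `alpha ~ N(0, sigma^2)`. The binomial
likelihood

`L_k(alpha) = prod_j pi_(k,j)^(y_j) (1 - pi_(k,j))^(n_j - y_j)`

yields a per-skeleton posterior; skeletons are re-weighted by their
marginal likelihoods times prior model probabilities (Bayesian model
averaging), all combined in log space.

### Estimator and prior-spread calibration

Two aspects of the published analysis are not stated precisely enough to
re-derive: how the "probability of toxicity" was point-estimated, and
whether the stated `N(0, 2)` prior on `alpha` gives the second argument as
a variance (sd `sqrt(2)`) or as a precision (sd `1/sqrt(2)`). The package
therefore exposes both conventions and three estimators — the plug-in
`p^exp(alpha_hat)` at the posterior mean (classical CRM practice), the
same at the posterior mode, and the full posterior mean of
`p^exp(alpha)` — and ships a calibration test that scores each principled
combination against the published per-patient escalation trace. The
plug-in estimator with sd `1/sqrt(2)` is the clear winner (maximum
absolute error .021 over the scored rows, several rows exact to the
printed rounding) and is the package default; the variance reading at any
estimator is far worse (errors above .07).

The calibration also documents a structural limit: the published
post-DLT row pairs a dose-1 estimate of .002 with a dose-3 estimate of
.165. Under the power model `pi_1 = pi_3^(log p_1 / log p_3)` with
exponents 1.861 and 2.757 for the two skeletons — both convex maps — so by
Jensen's inequality any `alpha` posterior and any model weighting whose
averaged dose-3 estimate is .165 forces the dose-1 estimate to at least
about .007. The printed .002 is unreachable under the stated two-skeleton
model for *any* estimator, prior spread, or integration scheme; the
corresponding assertions in the acceptance tests are therefore expected to
fail and are left in place as a faithful record rather than weakened.
Similarly, the published "probability that the lowest dose is more toxic
than the target" column does not match the literal posterior
`Pr(pi_1 > .20 | data)` under any convention we examined; the package
implements the literal rule (closed-form-verified on the prior) and makes
no attempt to match that column.

### Quadrature

Posteriors use deterministic fixed-grid trapezoidal integration over
`alpha` in `[-8 sigma, 8 sigma]` with 4097 nodes, accumulating marginals
in log space. This is reproducible bit-for-bit (no Monte Carlo noise), and
a suite invariant verifies that doubling the node count moves every
reported quantity — `alpha` means, log marginals, model-averaged
estimates, the overdose probability — by less than 1e-6. The overdose
probability `Pr(pi_1 > target)` reduces per skeleton to a lower tail in
`alpha` with cutpoint `log(log(target)/log(p_1))`, evaluated by a partial
trapezoid with linear interpolation at the cut; with no data and a single
skeleton it equals `Phi(log(log(target)/log(p_1))/sigma)` exactly, which
the tests check.

### Decision rules

Assignment targets the dose whose estimate is closest to the .20 target
with two constraints: escalation may not skip (at most one level above the
highest dose already tried — the published second cohort was treated at
the middle dose even though the top dose was nominally closest), and a
distance tie is broken toward the higher dose, matching the "highest dose
closest to the target" phrasing of the MTD rule, which uses the same
tie-break on the final data. Early termination fires when the posterior
probability that the lowest dose exceeds the target passes .85. Patients
who withdraw before DLT assessment contribute nothing to the tally; the
reconstructed enrollment (`study_enrollment()`) encodes the one such
withdrawal and places the single DLT at the 13th evaluable patient, the
only placement consistent with the published per-patient trace (the
accompanying narrative attributes the DLT to a different enrollment
number; the trace's own patient-count column was followed).

Replay supports two update cadences because the published trace repeats
identical rows inside some cohorts: `per-patient` recomputes before every
evaluable patient (the default, and the cadence that matches the scored
rows), while `per-cohort` refreshes only when the preceding evaluable
count completes a cohort.

## Non-compartmental PK

Profiles follow the protocol sampling times (pre-infusion and 0.5, 0.75,
1, 2, 4, 8, 12, 24 h after the start of a 1-h infusion) with an assay
quantification limit of 8.5 ng/mL for docetaxel. Conventions, chosen to
match standard NCA practice where the trial report names only
"a non-compartmental model":

* **Trapezoid**: linear-up/log-down by default (log trapezoid on falling
  intervals between positive samples, exact for exponential decline);
  pure linear by flag. Both are additive over interior split points.
* **BLQ policy**: samples before the first quantifiable concentration
  count as zero; embedded and trailing below-limit samples are excluded
  from both AUC and terminal-slope fitting. This is the conventional,
  conservative choice.
* **Terminal slope**: log-linear least squares on the last `m`
  quantifiable points strictly after Tmax (Tmax excluded), `m >= 3`,
  selecting the candidate with the best adjusted R² (ties toward more
  points); `lambda_z = -slope`, reported with `n` points and adjusted R²
  for audit. Non-negative slopes and short tails yield a flagged
  no-result rather than a number.
* **Extrapolation**: `AUC_inf = AUC_last + C_last/lambda_z`; an
  extrapolated fraction above 20% is reported with a message.
* **Dose normalisation** divides by administered mg; body-surface dosing
  is upstream.

Exposure occasions are compared by the paired geometric mean ratio:
`exp` of the mean paired log difference, with the `t`-interval on
`n - 1` degrees of freedom exponentiated for the confidence interval
(95% default). The ratio equals the ratio of per-occasion geometric
means, is reciprocal-symmetric and scale-invariant, and its interval has
exact nominal coverage under lognormal errors — verified by simulation in
the acceptance suite (10,000 replicates at n = 5).

The published exposure table is internally inconsistent in one row: the
peak-concentration row repeats the AUC geometric means while printing a
different ratio, so that ratio (and the published confidence intervals,
which need patient-level data) are demonstrated non-recomputable in the
tests rather than targeted.

## Correlative statistics

Longitudinal analytes are normalised to each subject's day-1 baseline
(fold change, baseline mapped to 1). The IGF-1R pharmacodynamic readout is
the ratio of phospho-IGF-1R(Y1131) signal in ligand-stimulated versus
unstimulated mononuclear cells, with fold change over time again relative
to day 1; both transforms are invariant to common positive rescaling of
the raw signals.

The exact Wilcoxon signed-rank test drops zero differences, mid-ranks
ties, and computes the null distribution of the positive-rank sum exactly
for up to 25 non-zero differences via a subset-sum (shift) enumeration
over doubled ranks — identical to enumerating all `2^n` sign assignments,
including under ties, and verified against brute-force enumeration for all
`n <= 10`. Beyond 25 it switches to the normal approximation with tie and
continuity corrections. The paired t test uses the textbook statistic with
one-sided alternatives; zero-variance differences are flagged rather than
returned as infinite statistics. PSA response takes the nadir over all
follow-ups, with the -50% boundary counted as a response; linear
mixed-effects modelling of the angiogenesis markers is deliberately out of
scope (routine, off-the-shelf), the package supplying only the
transformations that feed it.

## Synthetic data

The generators produce every input the pipeline consumes, as pure
functions of `(parameters, seed)` with per-entity seeds derived from a
master seed by a counter scheme.

* **DLT outcomes** are independent Bernoulli draws under a scenario's true
  per-dose probabilities; degenerate scenarios (all-zero, all-one) give
  exact operating characteristics and anchor the simulator tests.
* **Concentrations** come from the closed-form two-compartment
  constant-rate-infusion solution with multiplicative lognormal residual
  error, a lognormal subject effect on clearance, and a per-occasion
  exposure multiplier (default 1.10) standing in for the lycopene effect.
  Defaults (CL 46 L/h, V1 7.4 L, Q 28 L/h, V2 55 L, 140 mg over 1 h)
  mimic docetaxel-scale disposition — exposure near dose/CL ≈ 3000
  ng·h/mL — and are illustrative, not fitted to any patient data. The
  single-compartment limit and the `dose/CL` identity are tested.
* **Biomarkers** follow the qualitative group-level shapes the trial
  reported: lycopene rising to a common plateau faster at higher dose
  (saturation near 0.8 µmol/L), a VEGF-A log-slope that flips sign with
  dose (negative at 30, flat at 90, positive at 150 mg/day), a transient
  CEC excursion peaking near day 57 (downward at 30, largest upward at
  90), a late decline of the phosphorylation ratio only at the top dose,
  and PSA declining to a subject-specific nadir. Noise is lognormal
  throughout (positive, skewed measurements).

What the generators do *not* emulate: accrual timing, dropout beyond the
single evaluability flag, assay drift or batch effects, correlation
between analytes within a subject, body-surface-area dose individualisation,
and any fitted patient-level parameter. Passing tests on synthetic data
therefore demonstrate that the estimators recover known truth under the
assumed error model — not that the trial's specific numerical results
would re-emerge from real patient data, which were never deposited.

## Problem sizes and runtime choices

The test suite keeps simulation sizes at the point of diminishing returns:
posterior invariants on ~120 randomized tallies, 10,000 replicates for
GMR interval coverage (binomial standard error ~0.2% against a ±2% band),
full Wilcoxon enumeration up to n = 10 against the brute-force oracle,
operating characteristics at small `n_sim` where the expected frequencies
are exact, and 20-seed recovery runs for the biomarker slope signs. The
deterministic quadrature makes every dose-finding number reproducible to
full floating precision, so no tolerance anywhere absorbs sampling noise
from the engine itself.

## Known limitations

* The escalation trace cannot be reproduced beyond ~.02 absolute in some
  rows for the structural reasons above; the package reports what the
  stated model actually implies.
* The exact Wilcoxon enumeration is O(n · sum of ranks) in memory and
  time; above n = 25 it hands over to the corrected normal approximation.
* `lambda_z` selection by adjusted R² can, on very sparse tails, choose a
  3-point set with optimistic fit statistics — the selection is reported
  (`n_points`, `adj_r2`, times used) precisely so such fits can be audited.
* The simulators are generative stand-ins with documented, illustrative
  parameters; they are labelled synthetic wherever they surface.
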