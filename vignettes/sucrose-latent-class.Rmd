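---
title: "Blood sucrose screening for gastric ulcers in foals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood sucrose screening for gastric ulcers in foals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sucroselc)
```

This vignette documents the statistical methods implemented in
`sucroselc`, the assumptions behind them, and the numerical and design
choices a maintainer would want to know about.  Everything shown here is
computed by the package at build time; no number is quoted from outside
the code.

## The clinical problem

Gastric ulceration is near-ubiquitous in foals around weaning, but the
reference examination — gastroscopy — requires fasting, sedation and
specialist equipment.  The blood sucrose permeability test is a simple
alternative: after an oral sucrose dose, sucrose appears in blood in
proportion to the permeability of the gastric mucosa, so an elevated
concentration at 45 or 90 minutes flags a compromised mucosal barrier.
The pipeline evaluates that screening test in a two-occasion cohort
design (each foal examined about a week before and two weeks after
weaning) with four binary gastroscopy outcomes per examination: any
gastric lesion (`gl`), glandular lesion (`gdl`), squamous lesion
(`sql`), and clinically significant lesion (`csl`).

## Frequentist accuracy analysis

**ROC and AUC.** A record is test-positive when its concentration is
greater than or equal to the cutoff; the empirical ROC curve has one
operating point per distinct observed concentration plus the (0,0)
endpoint.  The AUC point estimate is the Mann–Whitney statistic (ties
count one half), which equals the trapezoidal area under the empirical
curve — the test suite verifies that identity exhaustively.

**Cluster bootstrap.** Each foal contributes two correlated records, so
ordinary bootstrap intervals would be too narrow.  All intervals
(AUC, sensitivity, specificity, prevalence) are percentile intervals
over replicates that resample *foals* with replacement, each sampled
foal carrying both its occasions.  The default is 2000 replicates.
Numerical policies:

* the point estimate is always the statistic on the original sample;
  the bootstrap supplies only intervals and comparisons;
* a replicate in which only one disease class survives leaves the AUC
  undefined; such replicates are redrawn (at most 100 attempts, then an
  error) and the number of redraws is reported;
* the 45- vs 90-minute AUC comparison feeds the *same* resampled foals
  to both time points, and its two-sided bootstrap p-value is floored
  at `2 / n_boot` — the resolution of a finite bootstrap — and capped
  at 1;
* percentiles use linear interpolation between order statistics
  (R's default type-7 quantile).

**Cutoff selection.** Youden's index `Se + Sp - 1`, or the screening
variant `1.33 Se + 0.67 Sp - 1` that weights sensitivity twice as
heavily, is maximised over all observed thresholds; ties break toward
the lower threshold (higher sensitivity), and a `manual_max_se` rule
returns the largest threshold achieving maximal sensitivity with
non-zero specificity.  The package default cutoff of 24 µmol/L is the
value a screening analysis of this design selects for field use.

**Paired comparisons and rates.** The pre/post prevalence comparison
uses the exact McNemar test (binomial on discordant foals) rather than
a mixed-effects logistic regression: it is exact at n = 45, assumption
free, and respects the pairing.  The incidence rate is new cases per
foal-week among foals lesion-free at the first examination.
Inter-observer agreement is summarised as raw percent agreement and
Cohen's kappa; kappa is reported as `NA` (with a warning) when both
raters are constant, never silently zero.

## The Bayesian latent class model

With no perfect reference test, sensitivity and specificity are
estimated by a Hui–Walter latent class model: three tests
(sucrose 45, sucrose 90, gastroscopy) observed in two populations
(pre- and post-weaning) whose prevalences differ.  The two sucrose
measurements share biology — both reflect the same permeability state —
so they cannot be assumed conditionally independent given disease; the
model includes a pairwise covariance between them within each latent
class (`cov_se` given diseased, `cov_sp` given non-diseased).
Gastroscopy is conditionally independent of the sucrose tests given the
latent state.  Each covariance is constrained to the range that keeps
all four joint cell probabilities non-negative
(`cov_bounds()`); the cross-classified 2 × 8 count table is multinomial
within each population.

Two modelling notes worth flagging:

* The two populations are treated as independent multinomials even
  though the same foals appear in both — the classical Hui–Walter
  framing.  The report metadata flags this; a foal-level random effect
  is a documented extension point, not implemented.
* The constraint `Se3 + Sp3 > 1` (gastroscopy better than chance) is
  enforced by prior truncation.  It anchors the latent class to
  "disease" and prevents label switching; with the informative
  gastroscopy priors below it is rarely active, but small samples can
  otherwise flip chains.

**Priors** (`egus_priors()`): Beta(2, 8) and Beta(6, 4) for pre- and
post-weaning prevalence, Beta(8, 2) and Beta(99, 1) for gastroscopy
sensitivity and specificity, and uniform Beta(1, 1) for all four
sucrose parameters (the test under evaluation gets no prior help).
The covariances get uniform priors over their admissible ranges
evaluated at the current sensitivities/specificities — a standard
weakly-informative choice, since no published prior information exists
for the dependence terms.  `prior_table()` reproduces the elicitation
summary; one arithmetic discrepancy is documented in the package: the
95th percentile of Beta(2, 8) computes to 0.429 (confirmed by the
closed-form binomial-tail representation and by symmetry with the
Beta(8, 2) 5th percentile of 0.571), not the 0.388 sometimes quoted
for it.

```{r}
prior_table()[, 1:8]
```

**Sampler.** The posterior is sampled by random-walk
Metropolis-within-Gibbs over the ten parameters.  Probabilities are
proposed on the logit scale, covariances on the logit of their position
within the current admissible range; both transforms contribute the
appropriate Jacobian to the acceptance ratio.  Proposal scales adapt
toward 44% acceptance during burn-in only and are frozen afterwards, so
the retained chain is a valid Markov chain targeting the exact
posterior.  Initial values are drawn from the priors independently per
chain (over-dispersed starts), covariances start at zero.  The kernel
is implemented in C++ (Rcpp) — a desk-scale fit takes ~2–3 seconds.

Two schedules are provided: the production profile
(3 chains, burn-in 200,000 iterations, thinning 10, 40,000 retained
iterates per chain — "40,000 retained" is our reading of a schedule
sometimes stated ambiguously as "the subsequent 40,000") and a
ten-fold-shorter desk profile (burn-in 20,000, 4,000 retained per
chain) used throughout the tests and examples; on the problem sizes
involved (2 × 8 cell counts) the desk profile converges with
Gelman–Rubin statistics below 1.01.

**Inference.** Chains are pooled; point estimates are posterior
medians, intervals the 2.5th–97.5th percentiles (type-7 interpolation).
Convergence is assessed by the Gelman–Rubin potential scale reduction
factor computed from between- and within-chain variances of the
retained iterates; zero within-chain variance is flagged as undefined
and zero between-chain variance as degenerate, rather than silently
returning 1.

**Correctness anchors.** The sampler is validated three independent
ways in the test suite: (i) a reduced model with all accuracies fixed
leaves two independent one-dimensional posteriors that are integrated
on a dense grid — MCMC medians agree within 0.01; (ii) with counts
simulated from known parameters at n = 1000 per population, all ten
posterior medians recover truth within ±0.07 with R-hat < 1.1;
(iii) on the conditional-independence submodel the posterior is
cross-checked against an independent JAGS implementation.

## The synthetic cohort generator

No raw foal data were ever published, so `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes:

* **Latent disease, monotone over weaning.** The true lesion state is
  Bernoulli(0.21) pre-weaning; affected foals stay affected (no
  spontaneous healing within the three-week window, consistent with the
  observed incidence of roughly 30% new cases per foal-week) and
  unaffected foals convert with the probability that makes the marginal
  post-weaning prevalence 0.98.
* **Concentrations are bivariate lognormal given the latent state**,
  moment-matched to the published group means/SDs (normal foals
  23.99 ± 17.91 µmol/L at 45 min, 23.83 ± 13.26 at 90 min; lesioned
  foals 57.56 ± 41.30 and 54.84 ± 36.58).  Lognormality is a modelling
  choice — concentrations are positive and right-skewed; no
  distributional family was reported — and `moment_match_lognormal()`
  makes the match exact in mean and SD.
* **Correlation calibration.** The observed 45/90-minute Spearman
  correlation (≈ 0.935) is a *pooled* quantity: it mixes the
  within-class association with the between-class mean shift.  The
  generator therefore uses a within-class log-scale correlation of
  0.91, chosen once by simulation at large n so that the pooled
  Spearman correlation of a default cohort lands at ≈ 0.935.
* **Gastroscopy is imperfect** (Se 0.81, Sp 0.99 against the latent
  state) — the latent class analysis requires truth to be distinct from
  the reference test.  Lesion subtypes are drawn only when `gl = 1`
  (probabilities 0.60/0.95/0.83 for gdl/sql/csl, chosen to reproduce
  the relative post-weaning subtype frequencies), so subtype indicators
  never contradict the parent lesion flag.  Concentrations are keyed on
  the single latent gastric-lesion state; the published per-subtype
  means overlap heavily (a squamous-lesion foal is almost always also a
  gastric-lesion foal) and carry no extra identifiable signal.

What the generator does **not** emulate: within-foal correlation of
sucrose concentrations *across occasions* (each occasion draws fresh
values given the latent state), age/weight covariates, assay
measurement error as a separate component, and any pharmacokinetics —
concentrations are drawn, not mechanistically simulated.  Passing tests
therefore demonstrate that the pipeline recovers the parameters of this
generative structure, not that the sucrose test performs identically in
new field data.

## Numerical choices and degenerate inputs

* Beta quantiles come from numerical inversion of the regularised
  incomplete beta function (`stats::qbeta`, absolute error well below
  1e-6); the tests cross-check integer-shape cases against the
  closed-form binomial-tail representation.
* Display rounding is half-away-from-zero to match conventional table
  display; full-precision values are always retained alongside.
* `dichotomize()` rejects non-positive concentrations; a concentration
  exactly at the cutoff is positive.
* Spearman's rho uses average ranks for ties and refuses constant
  vectors rather than returning `NaN`.
* Empty populations are legal in the latent class counts (the
  likelihood term vanishes and the posterior reverts to the prior) —
  that is what makes prior-recovery checks possible.
* Master-seed fan-out in `run_study()`: stage *k* runs with seed
  `(seed * 1000 + k) mod (2^31 - 1)`, and every stage seed is recorded
  in the report metadata.

## Problem sizes used in the tests

Unit tests run on cohorts of 5–500 foals and counts of 100–1000 per
population with the desk MCMC profile; the Monte-Carlo fidelity checks
use 2000–50,000 foals.  These sizes were chosen so the full suite
exercises every stage, including three-chain MCMC fits, in under a
minute on a single core while leaving all statistical tolerances
comfortably wide relative to their Monte-Carlo error.

## Known limitations

* The pairwise-dependence model covers the two sucrose tests only; more
  than pairwise dependence, more than three tests, or more than two
  populations would need the general Dendukuri-style covariance
  structure.
* The cluster bootstrap treats foals as exchangeable clusters; it does
  not model occasion as a fixed effect.
* The latent class model ignores that the two populations share foals
  (see above).
* Agreement statistics are pairwise only (no multi-rater kappa).
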