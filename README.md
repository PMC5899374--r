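# sucroselc

Diagnostic-accuracy analysis of blood sucrose as a screening test for
equine gastric ulcer syndrome (EGUS) in weanling foals.

Gastroscopy, the reference examination for gastric lesions, is invasive
and expensive; a blood sucrose concentration measured 45 or 90 minutes
after an oral sucrose dose is a cheap field alternative, because a
compromised gastric mucosal barrier lets more sucrose through.  Two
problems make the evaluation of such a screening test statistically
interesting:

1. **Repeated measures.** Each foal is examined twice (before and after
   weaning), so naive confidence intervals for ROC areas, sensitivity,
   specificity and prevalence are too narrow.  `sucroselc` handles this
   with a *foal-level cluster bootstrap*: whole foals — both of their
   occasions — are resampled with replacement.
2. **No gold standard.** Gastroscopy itself is imperfect, so
   "sensitivity against gastroscopy" understates the sucrose test.
   `sucroselc` therefore also fits a Bayesian **Hui–Walter latent class
   model**: three tests (sucrose at 45 min, sucrose at 90 min,
   gastroscopy) observed in two populations with different prevalence
   (pre-/post-weaning) identify all test accuracies and both prevalences
   without assuming any test is perfect.

For tests `t = 1..3` with sensitivities `Se_t`, specificities `Sp_t`,
population prevalences `pi_p`, and a conditional covariance between the
two sucrose tests (`cov_se` given disease, `cov_sp` given no disease),
the probability of observing pattern `(i, j, k)` in population `p` is

```
P(i,j,k | p) = pi_p  * [Se1^i (1-Se1)^(1-i) Se2^j (1-Se2)^(1-j) + d(i,j) cov_se] * Se3^k (1-Se3)^(1-k)
         + (1-pi_p) * [(1-Sp1)^i Sp1^(1-i) (1-Sp2)^j Sp2^(1-j) + d(i,j) cov_sp] * (1-Sp3)^k Sp3^(1-k)
```

with `d(i,j) = +1` if `i = j`, else `-1`.  The cross-classified counts
are multinomial; Beta priors (mildly informative for prevalence and
gastroscopy, uniform for the sucrose tests) complete the posterior,
which is sampled by an adaptive Metropolis-within-Gibbs algorithm with
Gelman–Rubin convergence diagnostics.

Because the original cohort data were never published, the package ships
a synthetic-cohort generator (`simulate_cohort()`) that reproduces the
study's design and summary statistics — 45 foals tested on 2 occasions,
lesion prevalence rising from 21% to 98% over weaning, lognormal sucrose
concentrations moment-matched to the published group means/SDs, and a
45/90-minute Spearman correlation near 0.935 — so every stage of the
pipeline is testable end to end.

## Worked example

```r
library(sucroselc)

cohort <- simulate_cohort(sim_config(), seed = 1)   # 45 foals x 2 occasions

spearman_rho(cohort$sucrose45, cohort$sucrose90)
#> [1] 0.949

prevalence(cohort, "gl", "pre", n_boot = 2000, seed = 2)
#>   lesion occasion estimate conf.low conf.high     n
#> 1 gl     pre         0.222    0.111     0.356    45

cluster_bootstrap_auc(cohort, "gl", time = 45, n_boot = 2000, seed = 3)
#>   lesion  time   auc conf.low conf.high n_boot n_redraws
#> 1 gl        45 0.715    0.614     0.817   2000         0

se_sp_at_cutoff(cohort, "gl", time = 45, cutoff = 24, n_boot = 2000, seed = 4)
#>   lesion  time cutoff sensitivity se.low se.high specificity sp.low sp.high
#> 1 gl        45     24       0.889    0.8   0.976       0.467  0.326   0.614

fit <- run_mcmc(cross_classify(cohort, "gl", cutoff = 24),
                profile = "desk", seed = 5)
tidy(fit)
#>    term   estimate conf.low conf.high  rhat
#>  1 pi1      0.235    0.123      0.387 1.00
#>  2 pi2      0.850    0.703      0.948 1.00
#>  3 se1      0.888    0.772      0.958 1.00
#>  4 sp1      0.541    0.366      0.715 1.00
#>  5 se2      0.875    0.757      0.950 1.00
#>  6 sp2      0.577    0.398      0.753 1.00
#>  7 se3      0.856    0.718      0.964 1.00
#>  8 sp3      0.992    0.958      1.000 1.00
#>  9 cov_se   0.0767   0.0268     0.148 1.00
#> 10 cov_sp   0.162    0.0918     0.212 1.00
```

Reading the output: on this synthetic cohort the observed (gold
standard) pre-weaning prevalence is 22% (true latent value 21%); the
45-minute sucrose AUC against gastroscopy is 0.72; at the 24 µmol/L
cutoff sensitivity is 89% but apparent specificity only 47%.  The
latent class model, which does not trust gastroscopy, estimates
gastroscopy's own sensitivity at 86% and pushes the sucrose
specificities up relative to the gold-standard analysis — exactly the
pattern that motivates the no-gold-standard model.  All R-hat values
sit at 1.00, indicating converged chains.

`run_study()` wraps all of these stages (plus the McNemar pre/post
comparison, AUC comparison, cutoff selection, incidence rate and the
other three lesion outcomes) into one reproducible report driven by a
single master seed, and `autoplot()` draws ROC curves and posterior
trace plots.  A thin command-line front end with `simulate`, `priors`,
`roc`, `lc-fit` and `report` subcommands lives at
`inst/cli/sucroselc.R`.

## Methods documentation

`vignettes/sucrose-latent-class.Rmd` describes the model, the priors,
the sampler, the synthetic-data generator and the package's numerical
and design choices in detail.
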