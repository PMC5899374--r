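# Shared fixtures, all built in code.

# 5 foals x 2 occasions with known 2x2 classification of sucrose45 vs gl at
# the 24 umol/L cutoff: diseased records (gl = 1) have sucrose45
# 30, 25, 10, 24 (3 positive of 4); healthy records 10, 23.9, 24.5, 12, 5,
# 40 (2 positive of 6).  Hand-counted: Se = 3/4, Sp = 4/6.
toy_cohort <- function() {
  tibble::tibble(
    foal_id = rep(sprintf("F%02d", 1:5), each = 2),
    occasion = rep(c("pre", "post"), times = 5),
    sucrose45 = c(30, 25, 10, 24, 10, 23.9, 24.5, 12, 5, 40),
    sucrose90 = c(28, 26, 12, 22, 11, 20.0, 23.0, 14, 7, 38),
    gl = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    gdl = 0L, sql = 0L, csl = 0L
  )
}

# truth used for forward simulation / recovery checks: prevalences and test
# accuracies at the magnitudes the latent class analysis reports, plus
# small positive conditional covariances inside the admissible ranges
truth_params <- function() {
  lc_parameters(pi1 = 0.42, pi2 = 0.92, se1 = 0.89, sp1 = 0.83,
                se2 = 0.81, sp2 = 0.95, se3 = 0.81, sp3 = 0.99,
                cov_se = 0.05, cov_sp = 0.02)
}

# random valid latent class parameters for property tests
random_lc_params <- function() {
  se3 <- stats::runif(1, 0.6, 0.98)
  sp3 <- stats::runif(1, max(0.6, 1 - se3 + 0.05), 0.98)
  p <- list(pi1 = stats::runif(1, 0.05, 0.95),
            pi2 = stats::runif(1, 0.05, 0.95),
            se1 = stats::runif(1, 0.05, 0.95),
            sp1 = stats::runif(1, 0.05, 0.95),
            se2 = stats::runif(1, 0.05, 0.95),
            sp2 = stats::runif(1, 0.05, 0.95),
            se3 = se3, sp3 = sp3)
  bse <- cov_bounds(p$se1, p$se2)
  bsp <- cov_bounds(p$sp1, p$sp2)
  p$cov_se <- stats::runif(1, bse$lower, bse$upper)
  p$cov_sp <- stats::runif(1, bsp$lower, bsp$upper)
  do.call(lc_parameters, p)
}

# trapezoidal area under an empirical ROC curve (independent of auc_point)
trapezoid_auc <- function(roc) {
  ord <- order(roc$fpr, roc$sensitivity)
  x <- roc$fpr[ord]
  y <- roc$sensitivity[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# random small two-class dataset for ROC oracles; ties likely
random_roc_data <- function(n = 12) {
  labels <- c(0L, 1L, stats::rbinom(n - 2, 1, 0.5))
  values <- sample(seq(0.5, 6, by = 0.5), n, replace = TRUE) +
    2 * labels * stats::rbinom(n, 1, 0.7)
  list(values = values, labels = labels)
}
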