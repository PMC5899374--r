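test_that("the sampler is deterministic given its seed", {
  cnt <- simulate_crossclassified(truth_params(), 100, 100, seed = 1)
  f1 <- run_mcmc(cnt, chains = 2, burn_in = 500, n_keep = 100, seed = 42)
  f2 <- run_mcmc(cnt, chains = 2, burn_in = 500, n_keep = 100, seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(cnt, chains = 2, burn_in = 500, n_keep = 100, seed = 43)
  expect_false(identical(f1$draws, f3$draws))
  # every retained iterate satisfies the parameter constraints
  d <- f1$draws
  expect_true(all(d[, 1:8, ] > 0 & d[, 1:8, ] < 1))
  expect_true(all(d[, "se3", ] + d[, "sp3", ] > 1))
  for (ch in 1:2) {
    b_se <- cov_bounds(d[, "se1", ch], d[, "se2", ch])
    expect_true(all(d[, "cov_se", ch] >= b_se$lower - 1e-12 &
                      d[, "cov_se", ch] <= b_se$upper + 1e-12))
  }
})

test_that("reduced-model posterior medians match dense grid integration", {
  truth <- truth_params()
  cnt <- simulate_crossclassified(truth, 200, 200, seed = 11)
  fixed <- list(se1 = 0.89, sp1 = 0.83, se2 = 0.81, sp2 = 0.95,
                se3 = 0.81, sp3 = 0.99, cov_se = 0.05, cov_sp = 0.02)
  fit <- run_mcmc(cnt, chains = 3, burn_in = 5000, n_keep = 2000, seed = 2,
                  fixed = fixed)
  est <- tidy(fit)
  expect_setequal(est$term, c("pi1", "pi2"))

  # independent oracle: with the accuracies fixed, the two prevalences have
  # independent 1-D posteriors; integrate each on a dense grid
  m <- matrix(cnt$count, nrow = 2, byrow = TRUE)
  grid <- seq(5e-5, 1 - 5e-5, length.out = 10000)
  cellp <- function(pi, cell) {
    i <- cell %/% 4; j <- (cell %/% 2) %% 2; k <- cell %% 2
    d <- if (i == j) 1 else -1
    dis <- ((if (i) 0.89 else 0.11) * (if (j) 0.81 else 0.19) + d * 0.05) *
      (if (k) 0.81 else 0.19)
    nod <- ((if (i) 0.17 else 0.83) * (if (j) 0.05 else 0.95) + d * 0.02) *
      (if (k) 0.01 else 0.99)
    pi * dis + (1 - pi) * nod
  }
  grid_median <- function(counts_row, a, b) {
    lp <- sapply(grid, function(pi) {
      sum(counts_row * log(sapply(0:7, cellp, pi = pi))) +
        stats::dbeta(pi, a, b, log = TRUE)
    })
    w <- exp(lp - max(lp))
    grid[which.min(abs(cumsum(w) / sum(w) - 0.5))]
  }
  expect_equal(est$estimate[est$term == "pi1"],
               grid_median(m[1, ], 2, 8), tolerance = 0.01)
  expect_equal(est$estimate[est$term == "pi2"],
               grid_median(m[2, ], 6, 4), tolerance = 0.01)
})

test_that("Gelman-Rubin separates converged from shifted chains", {
  set.seed(61)
  a <- matrix(stats::rnorm(1e4), ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(stats::rnorm(1e4), ncol = 1, dimnames = list(NULL, "x"))
  r <- gelman_rubin(list(a, b))$rhat
  expect_gt(r, 0.99)
  expect_lt(r, 1.05)
  shifted <- b + 10
  expect_gt(gelman_rubin(list(a, shifted))$rhat, 1.5)
  # duplicated chains are flagged as degenerate
  expect_warning(gelman_rubin(list(a, a)), "degenerate")
  # constant chains have undefined Rhat
  cons <- matrix(1, 100, 1, dimnames = list(NULL, "x"))
  expect_warning(r0 <- gelman_rubin(list(cons, cons)), "Zero within-chain")
  expect_true(is.na(r0$rhat))
  expect_error(gelman_rubin(list(a)), "at least 2")
})

test_that("posterior summaries use interpolated percentiles", {
  draws <- array(as.numeric(1:1000), dim = c(1000, 1, 1),
                 dimnames = list(NULL, "pi1", NULL))
  fake <- structure(list(
    draws = draws, acceptance = matrix(0.4, 1, 1),
    schedule = list(chains = 1L, burn_in = 0L, thin = 1L, n_keep = 1000L),
    priors = egus_priors(), counts = matrix(0, 2, 8),
    fixed = stats::setNames(as.list(rep(0.5, 9)),
                            setdiff(c("pi2", "se1", "sp1", "se2", "sp2",
                                      "se3", "sp3", "cov_se", "cov_sp"),
                                    NULL)),
    seed = 1L
  ), class = "lc_fit")
  s <- summarize_posterior(fake)
  expect_equal(s$median, 500.5)
  expect_equal(s$lower, 25.975)
  expect_equal(s$upper, 975.025)
  # constant chain: degenerate interval
  draws[] <- 7
  fake$draws <- draws
  s2 <- summarize_posterior(fake)
  expect_equal(unlist(s2[c("median", "lower", "upper")], use.names = FALSE),
               c(7, 7, 7))
})

test_that("summaries are invariant under chain relabelling", {
  cnt <- simulate_crossclassified(truth_params(), 150, 150, seed = 3)
  fit <- run_mcmc(cnt, chains = 3, burn_in = 1000, n_keep = 300, seed = 5)
  flipped <- fit
  flipped$draws <- fit$draws[, , c(3, 1, 2)]
  expect_equal(summarize_posterior(fit)[c("median", "lower", "upper")],
               summarize_posterior(flipped)[c("median", "lower", "upper")])
})

test_that("all-positive post-weaning counts push the prevalence up", {
  cnt <- simulate_crossclassified(truth_params(), 100, 100, seed = 7)
  fit0 <- run_mcmc(cnt, chains = 2, burn_in = 2000, n_keep = 800, seed = 8)
  more <- cnt
  idx <- more$population == "post" & more$t1 == 1 & more$t2 == 1 &
    more$t3 == 1
  more$count[idx] <- more$count[idx] + 200L
  fit1 <- run_mcmc(more, chains = 2, burn_in = 2000, n_keep = 800, seed = 8)
  m0 <- tidy(fit0)
  m1 <- tidy(fit1)
  expect_gte(m1$estimate[m1$term == "pi2"], m0$estimate[m0$term == "pi2"])
})

test_that("posterior matches an independent Gibbs-in-JAGS fit", {
  # independent-route cross-check on the conditional-independence submodel
  # (covariances fixed at 0), which JAGS can express directly
  truth <- truth_params()
  p0 <- lc_parameters(truth$pi1, truth$pi2, truth$se1, truth$sp1,
                      truth$se2, truth$sp2, truth$se3, truth$sp3)
  cnt <- simulate_crossclassified(p0, 400, 400, seed = 21)
  fit <- run_mcmc(cnt, chains = 2, burn_in = 5000, n_keep = 2000, seed = 9,
                  fixed = list(cov_se = 0, cov_sp = 0))
  est <- tidy(fit)

  model <- "
  model {
    for (p in 1:2) { n[p, 1:8] ~ dmulti(prob[p, 1:8], N[p]) }
    for (p in 1:2) {
      for (c in 1:8) {
        prob[p, c] <- pi[p] * (se1^i1[c] * (1-se1)^(1-i1[c])) *
                      (se2^i2[c] * (1-se2)^(1-i2[c])) *
                      (se3^i3[c] * (1-se3)^(1-i3[c])) +
                      (1-pi[p]) * ((1-sp1)^i1[c] * sp1^(1-i1[c])) *
                      ((1-sp2)^i2[c] * sp2^(1-i2[c])) *
                      ((1-sp3)^i3[c] * sp3^(1-i3[c]))
      }
    }
    pi[1] ~ dbeta(2, 8);  pi[2] ~ dbeta(6, 4)
    se1 ~ dbeta(1, 1);  sp1 ~ dbeta(1, 1)
    se2 ~ dbeta(1, 1);  sp2 ~ dbeta(1, 1)
    se3 ~ dbeta(8, 2);  sp3 ~ dbeta(99, 1)
  }"
  m <- matrix(cnt$count, nrow = 2, byrow = TRUE)
  g <- expand.grid(t3 = 0:1, t2 = 0:1, t1 = 0:1)[, 3:1]
  data <- list(n = m, N = rowSums(m), i1 = g$t1, i2 = g$t2, i3 = g$t3)
  jm <- rjags::jags.model(textConnection(model), data = data,
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 7))
  stats::update(jm, 4000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("pi", "se1", "sp1", "se2", "sp2",
                                    "se3", "sp3"), 8000,
                              progress.bar = "none")
  post <- do.call(rbind, lapply(samp, as.matrix))
  jags_med <- apply(post, 2, stats::median)
  cmp <- c(pi1 = "pi[1]", pi2 = "pi[2]", se1 = "se1", sp1 = "sp1",
           se2 = "se2", sp2 = "sp2", se3 = "se3", sp3 = "sp3")
  for (nm in names(cmp)) {
    expect_equal(est$estimate[est$term == nm],
                 unname(jags_med[cmp[[nm]]]), tolerance = 0.03)
  }
})
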