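test_that("cluster bootstrap point estimate is the full-sample statistic", {
  coh <- simulate_cohort(sim_config(n_foals = 45), seed = 7)
  res <- cluster_bootstrap_auc(coh, "gl", 45, n_boot = 200, seed = 3)
  expect_equal(res$auc, auc_point(coh$sucrose45, coh$gl))
  expect_true(res$conf.low <= res$auc + 1e-9)
  expect_true(res$conf.high >= res$auc - 1e-9)
  # reproducible
  expect_identical(res, cluster_bootstrap_auc(coh, "gl", 45, 200, seed = 3))
  # n_boot = 0: point only
  res0 <- cluster_bootstrap_auc(coh, "gl", 45, n_boot = 0)
  expect_true(is.na(res0$conf.low) && is.na(res0$conf.high))
})

test_that("a single-cluster dataset reproduces the point estimate exactly", {
  # one foal, discordant across occasions: every foal-level resample is the
  # original sample, so the bootstrap distribution is a point mass
  coh <- tibble::tibble(
    foal_id = "F1", occasion = c("pre", "post"),
    sucrose45 = c(10, 30), sucrose90 = c(12, 28),
    gl = c(0L, 1L), gdl = 0L, sql = 0L, csl = 0L
  )
  res <- cluster_bootstrap_auc(coh, "gl", 45, n_boot = 50, seed = 1)
  expect_equal(res$conf.low, res$auc)
  expect_equal(res$conf.high, res$auc)
})

test_that("perfect separation yields AUC 1 with upper bound 1", {
  coh <- toy_cohort()
  coh$sucrose45 <- ifelse(coh$gl == 1, 100 + seq_len(10), seq_len(10))
  res <- cluster_bootstrap_auc(coh, "gl", 45, n_boot = 100, seed = 2)
  expect_equal(res$auc, 1)
  expect_equal(res$conf.high, 1)
})

test_that("interval width shrinks with more foals", {
  w <- sapply(c(45, 450), function(n) {
    coh <- simulate_cohort(sim_config(n_foals = n), seed = 10)
    r <- cluster_bootstrap_auc(coh, "gl", 45, n_boot = 300, seed = 4)
    r$conf.high - r$conf.low
  })
  expect_lt(w[2], w[1])
})

test_that("paired AUC comparison is symmetric and calibrated", {
  coh <- simulate_cohort(sim_config(n_foals = 40), seed = 12)
  # identical tests: delta 0, p clipped to 1
  same <- coh
  same$sucrose90 <- same$sucrose45
  res <- compare_auc(same, "gl", n_boot = 100, seed = 5)
  expect_equal(res$delta, 0)
  expect_equal(res$p.value, 1)
  # antisymmetry under swapping the two time points
  swapped <- coh
  swapped$sucrose45 <- coh$sucrose90
  swapped$sucrose90 <- coh$sucrose45
  a <- compare_auc(coh, "gl", n_boot = 200, seed = 6)
  b <- compare_auc(swapped, "gl", n_boot = 200, seed = 6)
  expect_equal(a$delta, -b$delta)
  expect_equal(a$conf.low, -b$conf.high)
  expect_equal(a$p.value, b$p.value)
  # 45 min separates perfectly, 90 min is noise: delta CI excludes 0
  rigged <- coh
  rigged$sucrose45 <- ifelse(rigged$gl == 1, 100 + seq_len(nrow(rigged)),
                             seq_len(nrow(rigged)))
  set.seed(1)
  rigged$sucrose90 <- sample(rigged$sucrose45)
  res2 <- compare_auc(rigged, "gl", n_boot = 400, seed = 7)
  expect_gt(res2$conf.low, 0)
  expect_equal(res2$p.value, 2 / 400)  # floored at the bootstrap resolution
})

test_that("sensitivity and specificity at a cutoff match hand counts", {
  coh <- toy_cohort()
  res <- se_sp_at_cutoff(coh, "gl", 45, cutoff = 24, n_boot = 100, seed = 8)
  expect_equal(res$sensitivity, 3 / 4)
  expect_equal(res$specificity, 4 / 6)
  expect_equal(res$youden, 3 / 4 + 4 / 6 - 1)
  expect_true(res$se.low <= res$sensitivity & res$sensitivity <= res$se.high)
  # cutoff below every value: everything positive
  res2 <- se_sp_at_cutoff(coh, "gl", 45, cutoff = 0.001, n_boot = 0)
  expect_equal(res2$sensitivity, 1)
  expect_equal(res2$specificity, 0)
  # perfect separation at the separating cutoff
  sep <- coh
  sep$sucrose45 <- ifelse(sep$gl == 1, 100, 10)
  res3 <- se_sp_at_cutoff(sep, "gl", 45, cutoff = 50, n_boot = 0)
  expect_equal(res3$sensitivity, 1)
  expect_equal(res3$specificity, 1)
})

test_that("prevalence estimates are raw proportions with valid intervals", {
  coh <- toy_cohort()
  # pre-weaning records: gl = 1, 1, 0, 0, 0 -> 0.4
  res <- prevalence(coh, "gl", "pre", n_boot = 200, seed = 9)
  expect_equal(res$estimate, 2 / 5)
  expect_true(res$conf.low <= res$estimate &
                res$estimate <= res$conf.high)
  all_pos <- coh
  all_pos$gl <- 1L
  expect_equal(prevalence(all_pos, "gl", "pre", n_boot = 0)$estimate, 1)
  expect_error(prevalence(coh[coh$occasion == "pre", ], "gl", "post"),
               "No records")
})

test_that("exact McNemar matches the binomial tail", {
  base <- tibble::tibble(
    foal_id = rep(sprintf("F%02d", 1:10), each = 2),
    occasion = rep(c("pre", "post"), 10),
    sucrose45 = 10, sucrose90 = 10,
    gdl = 0L, sql = 0L, csl = 0L
  )
  # all 10 discordant in one direction
  up <- base
  up$gl <- rep(c(0L, 1L), 10)
  res <- paired_prevalence_test(up, "gl")
  expect_equal(res$n_discordant, 10)
  expect_equal(res$p.value, 2 * 0.5^10)
  # no discordance
  conc <- base
  conc$gl <- rep(c(1L, 1L), 10)
  expect_equal(paired_prevalence_test(conc, "gl")$p.value, 1)
  # symmetric discordance 5/5
  sym <- base
  sym$gl <- c(rep(c(0L, 1L), 5), rep(c(1L, 0L), 5))
  expect_equal(paired_prevalence_test(sym, "gl")$p.value, 1)
})

test_that("incidence rate counts new cases per foal-week", {
  base <- tibble::tibble(
    foal_id = rep(sprintf("F%02d", 1:10), each = 2),
    occasion = rep(c("pre", "post"), 10),
    sucrose45 = 10, sucrose90 = 10,
    gdl = 0L, sql = 0L, csl = 0L
  )
  base$gl <- c(rep(c(0L, 1L), 6), rep(c(0L, 0L), 4))  # 6 of 10 convert
  res <- incidence_rate(base, "gl", weeks_between = 2)
  expect_equal(res$at_risk, 10)
  expect_equal(res$new_cases, 6)
  expect_equal(res$rate, 0.30)
  base$gl <- 0L
  expect_equal(incidence_rate(base, "gl", 2)$rate, 0)
  base$gl <- rep(c(1L, 1L), 10)
  expect_error(incidence_rate(base, "gl", 2), "at risk")
})

test_that("incidence on the default generator matches its closed form", {
  # monotone progression: E[rate] = (prev_post - prev_pre)/((1 - prev_pre) * weeks)
  coh <- simulate_cohort(sim_config(n_foals = 4000), seed = 13)
  wide <- tidyr::pivot_wider(coh[c("foal_id", "occasion", "latent_state")],
                             names_from = "occasion",
                             values_from = "latent_state")
  at_risk <- sum(wide$pre == 0)
  rate <- sum(wide$pre == 0 & wide$post == 1) / (at_risk * 3)
  expected <- (0.98 - 0.21) / ((1 - 0.21) * 3)
  se <- sqrt(expected * 3 / at_risk) / 3
  expect_lt(abs(rate - expected), 4 * se)
})
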