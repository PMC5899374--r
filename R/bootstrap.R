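lesion_cols <- c("gl", "gdl", "sql", "csl")

check_cohort <- function(data) {
  need <- c("foal_id", "occasion", "sucrose45", "sucrose90", lesion_cols)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("Cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}

sucrose_col <- function(time) {
  time <- as.character(time)
  if (!time %in% c("45", "90")) {
    stop("`time` must be 45 or 90.", call. = FALSE)
  }
  paste0("sucrose", time)
}

# Pre-computed row indices per foal; a bootstrap replicate samples FOALS
# with replacement and carries every record (both occasions) of each
# sampled foal, preserving the repeated-measures structure.
foal_index <- function(data) {
  split(seq_len(nrow(data)), data$foal_id)
}

resample_rows <- function(idx) {
  unlist(idx[sample.int(length(idx), replace = TRUE)], use.names = FALSE)
}

# Draw a replicate whose rows satisfy `ok`; replicates that do not (e.g. a
# single disease class, making the AUC undefined) are redrawn up to
# `max_tries` times and the number of redraws is reported.
resample_until <- function(idx, ok, max_tries = 100L) {
  redraws <- 0L
  for (i in seq_len(max_tries)) {
    rows <- resample_rows(idx)
    if (ok(rows)) return(list(rows = rows, redraws = redraws))
    redraws <- redraws + 1L
  }
  stop("Could not draw a valid bootstrap replicate in ", max_tries,
       " attempts.", call. = FALSE)
}

boot_ci <- function(stats, conf.level = 0.95) {
  a <- (1 - conf.level) / 2
  stats::quantile(stats, probs = c(a, 1 - a), names = FALSE, type = 7)
}

#' Cluster-bootstrap AUC with confidence interval
#'
#' The AUC point estimate is the Mann-Whitney statistic on the full sample
#' ([auc_point()]).  The confidence interval is a percentile bootstrap that
#' resamples foals (not records) with replacement, carrying both occasions
#' of every sampled foal, which respects the repeated-measures design.
#' Replicates in which only one disease class survives are redrawn (up to
#' 100 attempts) and counted.
#'
#' @param data A foal-occasion cohort tibble.
#' @param lesion Gastroscopy outcome defining disease: `"gl"`, `"gdl"`,
#'   `"sql"` or `"csl"`.
#' @param time Sucrose sampling time, 45 or 90 (minutes).
#' @param n_boot Number of bootstrap replicates (default 2000); 0 gives
#'   the point estimate only.
#' @param seed Integer seed.
#' @param conf.level Interval mass (default 0.95).
#' @return A one-row tibble: `lesion`, `time`, `auc`, `conf.low`,
#'   `conf.high`, `n_boot`, `n_redraws`.
#' @export
cluster_bootstrap_auc <- function(data, lesion = "gl", time = 45,
                                  n_boot = 2000L, seed = 1L,
                                  conf.level = 0.95) {
  check_cohort(data)
  lesion <- match.arg(lesion, lesion_cols)
  col <- sucrose_col(time)
  values <- data[[col]]
  labels <- data[[lesion]]
  point <- auc_point(values, labels)

  lo <- hi <- NA_real_
  redraws <- 0L
  if (n_boot > 0) {
    old <- local_rng_seed(as.integer(seed))
    on.exit(restore_rng(old), add = TRUE)
    idx <- foal_index(data)
    ok <- function(rows) length(unique(labels[rows])) == 2L
    reps <- vapply(seq_len(n_boot), function(b) {
      r <- resample_until(idx, ok)
      redraws <<- redraws + r$redraws
      auc_point(values[r$rows], labels[r$rows])
    }, numeric(1))
    ci <- boot_ci(reps, conf.level)
    lo <- ci[1]; hi <- ci[2]
  }
  tibble::tibble(lesion = lesion, time = as.integer(as.character(time)),
                 auc = point, conf.low = lo, conf.high = hi,
                 n_boot = as.integer(n_boot), n_redraws = redraws)
}

#' Paired bootstrap comparison of the 45- and 90-minute AUCs
#'
#' Within each bootstrap replicate the SAME resampled foals feed both the
#' 45- and the 90-minute AUC, so the difference
#' `delta = AUC(45) - AUC(90)` is estimated on paired replicates.  The
#' p-value is the two-sided bootstrap tail probability
#' `2 * min(P(delta* <= 0), P(delta* >= 0))`, floored at `2 / n_boot` (the
#' resolution of a finite bootstrap) and capped at 1.
#'
#' @inheritParams cluster_bootstrap_auc
#' @return A one-row tibble: `lesion`, `delta` (full-sample difference),
#'   `conf.low`, `conf.high`, `p.value`, `n_boot`, `n_redraws`.
#' @export
compare_auc <- function(data, lesion = "gl", n_boot = 2000L, seed = 1L,
                        conf.level = 0.95) {
  check_cohort(data)
  lesion <- match.arg(lesion, lesion_cols)
  stopifnot(n_boot >= 1)
  labels <- data[[lesion]]
  v45 <- data$sucrose45
  v90 <- data$sucrose90
  point <- auc_point(v45, labels) - auc_point(v90, labels)

  old <- local_rng_seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)
  idx <- foal_index(data)
  ok <- function(rows) length(unique(labels[rows])) == 2L
  redraws <- 0L
  reps <- vapply(seq_len(n_boot), function(b) {
    r <- resample_until(idx, ok)
    redraws <<- redraws + r$redraws
    auc_point(v45[r$rows], labels[r$rows]) -
      auc_point(v90[r$rows], labels[r$rows])
  }, numeric(1))
  ci <- boot_ci(reps, conf.level)
  p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
  p <- min(1, max(p, 2 / n_boot))
  tibble::tibble(lesion = lesion, delta = point,
                 conf.low = ci[1], conf.high = ci[2], p.value = p,
                 n_boot = as.integer(n_boot), n_redraws = redraws)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Gold-standard framing: sensitivity is the proportion of
#' gastroscopy-diseased records that are sucrose-positive at the cutoff,
#' specificity the proportion of gastroscopy-healthy records that are
#' sucrose-negative.  Percentile confidence intervals come from the
#' foal-level cluster bootstrap; replicates missing a disease class are
#' redrawn.
#'
#' @inheritParams cluster_bootstrap_auc
#' @param cutoff Sucrose positivity cutoff in umol/L (default 24).
#' @return A one-row tibble: `lesion`, `time`, `cutoff`, `sensitivity`,
#'   `se.low`, `se.high`, `specificity`, `sp.low`, `sp.high`, `youden`,
#'   `weighted_youden`, `n_boot`.
#' @export
se_sp_at_cutoff <- function(data, lesion = "gl", time = 45, cutoff = 24,
                            n_boot = 2000L, seed = 1L, conf.level = 0.95) {
  check_cohort(data)
  lesion <- match.arg(lesion, lesion_cols)
  col <- sucrose_col(time)
  pos <- dichotomize(data[[col]], cutoff)
  labels <- check_labels(data[[lesion]])
  se_sp <- function(rows) {
    c(se = mean(pos[rows][labels[rows] == 1L]),
      sp = mean(1 - pos[rows][labels[rows] == 0L]))
  }
  est <- se_sp(seq_len(nrow(data)))

  se_ci <- sp_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- local_rng_seed(as.integer(seed))
    on.exit(restore_rng(old), add = TRUE)
    idx <- foal_index(data)
    ok <- function(rows) length(unique(labels[rows])) == 2L
    reps <- vapply(seq_len(n_boot), function(b) {
      se_sp(resample_until(idx, ok)$rows)
    }, numeric(2))
    se_ci <- boot_ci(reps["se", ], conf.level)
    sp_ci <- boot_ci(reps["sp", ], conf.level)
  }
  tibble::tibble(
    lesion = lesion, time = as.integer(as.character(time)), cutoff = cutoff,
    sensitivity = unname(est["se"]), se.low = se_ci[1], se.high = se_ci[2],
    specificity = unname(est["sp"]), sp.low = sp_ci[1], sp.high = sp_ci[2],
    youden = unname(youden(est["se"], est["sp"])),
    weighted_youden = unname(weighted_youden(est["se"], est["sp"])),
    n_boot = as.integer(n_boot)
  )
}

#' Lesion prevalence with cluster-bootstrap confidence interval
#'
#' Raw proportion of gastroscopy-positive records at one occasion, with a
#' percentile interval from resampling foals.
#'
#' @inheritParams cluster_bootstrap_auc
#' @param occasion `"pre"` or `"post"`.
#' @return A one-row tibble: `lesion`, `occasion`, `estimate`, `conf.low`,
#'   `conf.high`, `n`.
#' @export
prevalence <- function(data, lesion = "gl", occasion = "pre",
                       n_boot = 2000L, seed = 1L, conf.level = 0.95) {
  check_cohort(data)
  lesion <- match.arg(lesion, lesion_cols)
  occasion <- match.arg(occasion, c("pre", "post"))
  sub <- data[data$occasion == occasion, ]
  if (nrow(sub) == 0L) {
    stop("No records for occasion \"", occasion, "\".", call. = FALSE)
  }
  y <- sub[[lesion]]
  est <- mean(y)
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    old <- local_rng_seed(as.integer(seed))
    on.exit(restore_rng(old), add = TRUE)
    idx <- foal_index(sub)
    reps <- vapply(seq_len(n_boot), function(b) {
      mean(y[resample_rows(idx)])
    }, numeric(1))
    ci <- boot_ci(reps, conf.level)
    lo <- ci[1]; hi <- ci[2]
  }
  tibble::tibble(lesion = lesion, occasion = occasion, estimate = est,
                 conf.low = lo, conf.high = hi, n = nrow(sub))
}

# foals with records at both occasions, as a wide tibble of pre/post status
paired_status <- function(data, lesion) {
  wide <- data |>
    dplyr::select("foal_id", "occasion", dplyr::all_of(lesion)) |>
    tidyr::pivot_wider(names_from = "occasion",
                       values_from = dplyr::all_of(lesion))
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("Paired analysis needs foals observed at both occasions.",
         call. = FALSE)
  }
  wide <- wide[!is.na(wide$pre) & !is.na(wide$post), ]
  if (nrow(wide) == 0L) {
    stop("No foal has complete pre and post records.", call. = FALSE)
  }
  wide
}

#' Exact paired comparison of pre- and post-weaning lesion status
#'
#' Exact McNemar test: conditional on the number of discordant foals, the
#' count changing in one direction is Binomial(n_discordant, 1/2) under the
#' null of equal prevalence; the p-value is the exact two-sided binomial
#' probability.
#'
#' @param data A foal-occasion cohort with both occasions.
#' @param lesion Lesion column.
#' @return A one-row tibble: `lesion`, `n_pairs`, `n_discordant`,
#'   `statistic` (foals converting negative -> positive), `p.value`.
#' @export
paired_prevalence_test <- function(data, lesion = "gl") {
  check_cohort(data)
  lesion <- match.arg(lesion, lesion_cols)
  wide <- paired_status(data, lesion)
  b <- sum(wide$pre == 0 & wide$post == 1)  # new cases
  c_ <- sum(wide$pre == 1 & wide$post == 0)
  nd <- b + c_
  p <- if (nd == 0) 1 else stats::binom.test(b, nd, 0.5)$p.value
  tibble::tibble(lesion = lesion, n_pairs = nrow(wide),
                 n_discordant = nd, statistic = b, p.value = p)
}

#' Incidence rate of new lesion cases
#'
#' New cases per foal-week: foals lesion-free pre-weaning that are
#' lesion-positive post-weaning, divided by the number at risk times the
#' weeks between samplings.
#'
#' @param data A foal-occasion cohort with both occasions.
#' @param lesion Lesion column.
#' @param weeks_between Weeks between the two samplings (default 3: 7 days
#'   before to 14 days after weaning).
#' @return A one-row tibble: `lesion`, `at_risk`, `new_cases`, `rate`
#'   (per foal-week).
#' @export
incidence_rate <- function(data, lesion = "gl", weeks_between = 3) {
  check_cohort(data)
  lesion <- match.arg(lesion, lesion_cols)
  if (!is.numeric(weeks_between) || weeks_between <= 0) {
    stop("`weeks_between` must be positive.", call. = FALSE)
  }
  wide <- paired_status(data, lesion)
  at_risk <- sum(wide$pre == 0)
  if (at_risk == 0L) {
    stop("No foals at risk (all lesion-positive pre-weaning).",
         call. = FALSE)
  }
  new_cases <- sum(wide$pre == 0 & wide$post == 1)
  tibble::tibble(lesion = lesion, at_risk = at_risk,
                 new_cases = new_cases,
                 rate = new_cases / (at_risk * weeks_between))
}
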