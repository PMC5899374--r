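#' Moment-match a lognormal to a target mean and SD
#'
#' Converts a mean/SD pair on the concentration scale into the log-scale
#' parameters of the lognormal distribution with exactly that mean and SD:
#' `log_sigma^2 = log(1 + sd^2/mean^2)` and
#' `log_mu = log(mean) - log_sigma^2 / 2`.
#'
#' @param mean,sd Strictly positive mean and standard deviation
#'   (concentration units, e.g. umol/L).
#' @return A one-row tibble with columns `log_mu` and `log_sigma`.
#' @examples
#' moment_match_lognormal(23.99, 17.91)
#' @export
moment_match_lognormal <- function(mean, sd) {
  p <- lnorm_params(mean, sd)
  tibble::tibble(log_mu = p[["log_mu"]], log_sigma = p[["log_sigma"]])
}

lnorm_params <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || length(mean) != 1L ||
      length(sd) != 1L || !is.finite(mean) || !is.finite(sd) ||
      mean <= 0 || sd <= 0) {
    stop("`mean` and `sd` must be finite and strictly positive.",
         call. = FALSE)
  }
  s2 <- log(1 + sd^2 / mean^2)
  c(log_mu = log(mean) - s2 / 2, log_sigma = sqrt(s2))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a probability in [0, 1].", call. = FALSE)
  }
  x
}

check_mean_sd <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be a positive (mean, sd) pair.", call. = FALSE)
  }
  x
}

#' Configuration for the synthetic foal cohort
#'
#' Defaults reproduce the design and summary statistics of the weanling-foal
#' study the pipeline targets: 45 foals gastroscoped and sucrose-tested once
#' before and once after weaning, gastric lesion prevalence rising from 21%
#' pre-weaning to 98% post-weaning, lognormal blood sucrose concentrations
#' moment-matched to the published group means/SDs at 45 and 90 min, a
#' within-group log-scale correlation of 0.91 between the two sampling times
#' (which yields a pooled Spearman correlation of about 0.935 once the
#' disease mean-shift is mixed in), and gastroscopy operating at
#' sensitivity 0.81 / specificity 0.99.
#'
#' @param n_foals Number of foals (each contributes two occasions).
#' @param prev_pre,prev_post True lesion prevalence before and after
#'   weaning; `prev_post >= prev_pre` (disease is modelled as monotone over
#'   weaning: affected foals do not heal within the three-week window).
#' @param mean_sd_normal_45,mean_sd_normal_90 `(mean, sd)` of sucrose
#'   concentration (umol/L) in lesion-free foals at 45 and 90 min.
#' @param mean_sd_diseased_45,mean_sd_diseased_90 Same for foals with
#'   gastric lesions.
#' @param log_corr Correlation between the log concentrations at 45 and
#'   90 min within a disease class, in (-1, 1).
#' @param endo_se,endo_sp Sensitivity and specificity of gastroscopy with
#'   respect to the true (latent) lesion state.
#' @param subtype_probs Named probabilities `gdl`, `sql`, `csl`: conditional
#'   probability of each lesion subtype given a gastric lesion is present.
#' @param seed Optional integer seed stored with the configuration.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_foals = 45,
                       prev_pre = 0.21,
                       prev_post = 0.98,
                       mean_sd_normal_45 = c(23.99, 17.91),
                       mean_sd_normal_90 = c(23.83, 13.26),
                       mean_sd_diseased_45 = c(57.56, 41.30),
                       mean_sd_diseased_90 = c(54.84, 36.58),
                       log_corr = 0.91,
                       endo_se = 0.81,
                       endo_sp = 0.99,
                       subtype_probs = c(gdl = 0.60, sql = 0.95, csl = 0.83),
                       seed = NULL) {
  if (!is.numeric(n_foals) || length(n_foals) != 1L || n_foals < 1 ||
      n_foals != round(n_foals)) {
    stop("`n_foals` must be a positive integer.", call. = FALSE)
  }
  check_prob(prev_pre, "prev_pre")
  check_prob(prev_post, "prev_post")
  if (prev_post < prev_pre) {
    stop("`prev_post` must be >= `prev_pre`: disease is monotone over weaning.",
         call. = FALSE)
  }
  check_mean_sd(mean_sd_normal_45, "mean_sd_normal_45")
  check_mean_sd(mean_sd_normal_90, "mean_sd_normal_90")
  check_mean_sd(mean_sd_diseased_45, "mean_sd_diseased_45")
  check_mean_sd(mean_sd_diseased_90, "mean_sd_diseased_90")
  if (!is.numeric(log_corr) || length(log_corr) != 1L ||
      abs(log_corr) >= 1) {
    stop("`log_corr` must lie strictly inside (-1, 1).", call. = FALSE)
  }
  check_prob(endo_se, "endo_se")
  check_prob(endo_sp, "endo_sp")
  if (!all(c("gdl", "sql", "csl") %in% names(subtype_probs))) {
    stop("`subtype_probs` must name gdl, sql and csl.", call. = FALSE)
  }
  for (nm in c("gdl", "sql", "csl")) check_prob(subtype_probs[[nm]], nm)
  structure(list(
    n_foals = as.integer(n_foals),
    prev_pre = prev_pre, prev_post = prev_post,
    mean_sd_normal_45 = mean_sd_normal_45,
    mean_sd_normal_90 = mean_sd_normal_90,
    mean_sd_diseased_45 = mean_sd_diseased_45,
    mean_sd_diseased_90 = mean_sd_diseased_90,
    log_corr = log_corr,
    endo_se = endo_se, endo_sp = endo_sp,
    subtype_probs = subtype_probs[c("gdl", "sql", "csl")],
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a foal cohort
#'
#' Generates one foal-occasion record per foal per occasion (pre- and
#' post-weaning).  The true lesion state is latent: it is drawn
#' Bernoulli(`prev_pre`) pre-weaning; affected foals stay affected
#' post-weaning while unaffected foals convert with probability
#' `(prev_post - prev_pre) / (1 - prev_pre)`, so the marginal post-weaning
#' prevalence equals `prev_post`.  Blood sucrose at 45 and 90 min is drawn
#' from a bivariate lognormal whose marginal mean/SD depend on the latent
#' state and whose log-scale correlation is `log_corr`.  The gastroscopy
#' outcome `gl` is drawn from the latent state through
#' (`endo_se`, `endo_sp`); lesion subtypes are drawn given `gl = 1` so that
#' subtype indicators never contradict `gl`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; overrides `config$seed` when given.  Required
#'   through one of the two routes.
#' @return A tibble with one row per foal-occasion and columns `foal_id`,
#'   `occasion` (`"pre"`/`"post"`), `sucrose45`, `sucrose90` (umol/L),
#'   `gl`, `gdl`, `sql`, `csl` (0/1) and `latent_state` (0/1, the simulated
#'   truth).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_foals = 10), seed = 1)
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config object.", call. = FALSE)
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    stop("Provide a `seed` (argument or in the config) for reproducibility.",
         call. = FALSE)
  }
  old <- local_rng_seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)

  n <- config$n_foals
  p_conv <- if (config$prev_pre < 1) {
    (config$prev_post - config$prev_pre) / (1 - config$prev_pre)
  } else 0
  latent_pre <- stats::rbinom(n, 1L, config$prev_pre)
  latent_post <- ifelse(latent_pre == 1L, 1L,
                        stats::rbinom(n, 1L, p_conv))

  ln_n45 <- lnorm_params(config$mean_sd_normal_45[1],
                         config$mean_sd_normal_45[2])
  ln_n90 <- lnorm_params(config$mean_sd_normal_90[1],
                         config$mean_sd_normal_90[2])
  ln_d45 <- lnorm_params(config$mean_sd_diseased_45[1],
                         config$mean_sd_diseased_45[2])
  ln_d90 <- lnorm_params(config$mean_sd_diseased_90[1],
                         config$mean_sd_diseased_90[2])

  draw_occ <- function(latent) {
    z1 <- stats::rnorm(n)
    z2 <- config$log_corr * z1 +
      sqrt(1 - config$log_corr^2) * stats::rnorm(n)
    s45 <- ifelse(latent == 1L,
                  exp(ln_d45["log_mu"] + ln_d45["log_sigma"] * z1),
                  exp(ln_n45["log_mu"] + ln_n45["log_sigma"] * z1))
    s90 <- ifelse(latent == 1L,
                  exp(ln_d90["log_mu"] + ln_d90["log_sigma"] * z2),
                  exp(ln_n90["log_mu"] + ln_n90["log_sigma"] * z2))
    p_pos <- ifelse(latent == 1L, config$endo_se, 1 - config$endo_sp)
    gl <- stats::rbinom(n, 1L, p_pos)
    sub <- vapply(c("gdl", "sql", "csl"), function(nm) {
      ifelse(gl == 1L,
             stats::rbinom(n, 1L, config$subtype_probs[[nm]]), 0L)
    }, integer(n))
    if (n == 1L) sub <- matrix(sub, nrow = 1L,
                               dimnames = list(NULL, c("gdl", "sql", "csl")))
    tibble::tibble(sucrose45 = s45, sucrose90 = s90, gl = gl,
                   gdl = sub[, "gdl"], sql = sub[, "sql"],
                   csl = sub[, "csl"], latent_state = as.integer(latent))
  }

  ids <- sprintf("F%03d", seq_len(n))
  pre <- dplyr::bind_cols(tibble::tibble(foal_id = ids, occasion = "pre"),
                          draw_occ(latent_pre))
  post <- dplyr::bind_cols(tibble::tibble(foal_id = ids, occasion = "post"),
                           draw_occ(latent_post))
  dplyr::bind_rows(pre, post) |>
    dplyr::arrange(.data$foal_id,
                   factor(.data$occasion, levels = c("pre", "post")))
}

# Save/set/restore .Random.seed so simulators are reproducible without
# clobbering the caller's RNG stream.
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate cross-classified test counts from the latent class model
#'
#' Forward simulation from the three-test, two-population latent class
#' model: for each population the 8-cell test-pattern probabilities are
#' computed with [cell_probabilities()] and a multinomial sample of the
#' requested size is drawn.
#'
#' @param params An [lc_parameters()] object.
#' @param n_pre,n_post Number of subjects sampled in the pre- and
#'   post-weaning populations (non-negative integers).
#' @param seed Integer seed.
#' @return A tibble of class `lc_counts` with columns `population`
#'   (`"pre"`/`"post"`), `t1`, `t2`, `t3` (0/1 pattern; `t1` = sucrose 45,
#'   `t2` = sucrose 90, `t3` = gastroscopy) and `count`; 16 rows in the
#'   lexicographic pattern order with `t1` most significant.
#' @examples
#' p <- lc_parameters(pi1 = 0.42, pi2 = 0.92, se1 = 0.89, sp1 = 0.83,
#'                    se2 = 0.81, sp2 = 0.95, se3 = 0.81, sp3 = 0.99)
#' simulate_crossclassified(p, n_pre = 45, n_post = 45, seed = 1)
#' @export
simulate_crossclassified <- function(params, n_pre, n_post, seed) {
  params <- validate_lc_parameters(params)
  for (nm in c("n_pre", "n_post")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop("`", nm, "` must be a non-negative integer.", call. = FALSE)
    }
  }
  old <- local_rng_seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)
  pm <- cell_prob_matrix(params)
  draw <- function(n, probs) {
    if (n == 0) rep(0L, 8L) else as.integer(stats::rmultinom(1, n, probs))
  }
  counts <- c(draw(n_pre, pm["pre", ]), draw(n_post, pm["post", ]))
  pat <- pattern_grid()
  out <- tibble::tibble(
    population = rep(c("pre", "post"), each = 8L),
    t1 = rep(pat$t1, 2L), t2 = rep(pat$t2, 2L), t3 = rep(pat$t3, 2L),
    count = counts
  )
  class(out) <- c("lc_counts", class(out))
  out
}

pattern_grid <- function() {
  idx <- 0:7
  list(t1 = idx %/% 4L, t2 = (idx %/% 2L) %% 2L, t3 = idx %% 2L)
}
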