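#' MCMC schedule profiles
#'
#' Two ready-made schedules for [run_mcmc()].  `"paper"` is the
#' full-length production schedule (burn-in 200,000 iterations, thinning
#' 10, 40,000 retained iterates per chain); `"desk"` is a ten-fold shorter
#' profile (burn-in 20,000, thinning 10, 4,000 retained per chain) that
#' converges on the problem sizes used in the package's tests and examples
#' in seconds.
#'
#' @param profile `"paper"` or `"desk"`.
#' @return A list with elements `chains`, `burn_in`, `thin`, `n_keep`.
#' @export
mcmc_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  switch(profile,
    paper = list(chains = 3L, burn_in = 200000L, thin = 10L, n_keep = 40000L),
    desk  = list(chains = 3L, burn_in = 20000L,  thin = 10L, n_keep = 4000L)
  )
}

#' Fit the latent class model by MCMC
#'
#' Samples the posterior of the three-test, two-population latent class
#' model (see [log_posterior()]) with an adaptive random-walk
#' Metropolis-within-Gibbs sampler.  Probability parameters are proposed on
#' the logit scale; the two conditional covariances on the logit of their
#' position within the admissible range ([cov_bounds()]).  Proposal scales
#' adapt toward a 44% acceptance rate during burn-in only and are frozen
#' afterwards, so the retained chain targets the exact posterior.
#'
#' Initial values are drawn from the priors independently per chain
#' (over-dispersed starting points), with both covariances started at 0;
#' draws violating the support (`se3 + sp3 <= 1` or a zero-probability
#' cell) are rejected and redrawn.
#'
#' @param counts An `lc_counts` tibble (16 rows) or 2 x 8 count matrix; see
#'   [cross_classify()] and [simulate_crossclassified()].  All-zero counts
#'   are allowed, in which case the posterior equals the prior (restricted
#'   to `se3 + sp3 > 1`).
#' @param priors A prior set; default [egus_priors()].
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param burn_in,thin,n_keep Burn-in iterations, thinning interval and
#'   number of retained post-thinning iterates per chain.
#' @param profile Optional shortcut: `"desk"` or `"paper"` (see
#'   [mcmc_profile()]); overrides `chains`/`burn_in`/`thin`/`n_keep`.
#' @param seed Integer master seed; chain c uses stream `seed + c - 1`.
#' @param fixed Optional named list of parameters to hold fixed (e.g.
#'   `list(se1 = 0.89, sp1 = 0.83, ...)`), used for reduced-model analyses.
#' @return An object of class `lc_fit`: list with `draws` (array
#'   n_keep x 10 x chains), `acceptance`, `schedule`, `priors`, `counts`,
#'   `seed`.
#' @examples
#' p <- lc_parameters(0.42, 0.92, 0.89, 0.83, 0.81, 0.95, 0.81, 0.99)
#' cnt <- simulate_crossclassified(p, 45, 45, seed = 1)
#' fit <- run_mcmc(cnt, chains = 2, burn_in = 2000, n_keep = 500, seed = 1)
#' tidy(fit)
#' @export
run_mcmc <- function(counts, priors = egus_priors(), chains = 3L,
                     burn_in = 20000L, thin = 10L, n_keep = 4000L,
                     profile = NULL, seed = 1L, fixed = NULL) {
  validate_prior_set(priors)
  if (!is.null(profile)) {
    sched <- mcmc_profile(profile)
    chains <- sched$chains; burn_in <- sched$burn_in
    thin <- sched$thin; n_keep <- sched$n_keep
  }
  stopifnot(chains >= 1, burn_in >= 0, thin >= 1, n_keep >= 1)
  n <- counts_matrix(counts)
  ab <- prior_ab_matrix(priors)

  fixed_mask <- rep(FALSE, 10L)
  fixed_vals <- rep(NA_real_, 10L)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), lc_param_names)
    if (length(bad)) {
      stop("Unknown fixed parameters: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(names(fixed), lc_param_names)
    fixed_mask[idx] <- TRUE
    fixed_vals[idx] <- unlist(fixed)
  }

  draws <- array(NA_real_, dim = c(n_keep, 10L, chains),
                 dimnames = list(NULL, lc_param_names, NULL))
  acceptance <- matrix(NA_real_, 10L, chains,
                       dimnames = list(lc_param_names, NULL))
  for (ch in seq_len(chains)) {
    old <- local_rng_seed(as.integer(seed) + ch - 1L)
    init <- draw_init(ab, fixed_mask, fixed_vals, n)
    res <- lc_mcmc_chain_cpp(n, ab, init, fixed_mask,
                             as.integer(burn_in), as.integer(thin),
                             as.integer(n_keep),
                             rep(0.5, 10L), TRUE)
    restore_rng(old)
    draws[, , ch] <- res$draws
    acceptance[, ch] <- res$acceptance
  }

  structure(list(
    draws = draws,
    acceptance = acceptance,
    schedule = list(chains = chains, burn_in = burn_in, thin = thin,
                    n_keep = n_keep),
    priors = priors,
    counts = n,
    fixed = fixed,
    seed = as.integer(seed)
  ), class = "lc_fit")
}

# Draw over-dispersed initial values from the priors; covariances start at
# 0 (always admissible for interior accuracies).
draw_init <- function(ab, fixed_mask, fixed_vals, counts) {
  for (attempt in 1:100) {
    init <- c(stats::rbeta(8, ab[, 1], ab[, 2]), 0, 0)
    # keep starting points away from the boundary for the logit transform
    init[1:8] <- pmin(pmax(init[1:8], 1e-4), 1 - 1e-4)
    init[fixed_mask] <- fixed_vals[fixed_mask]
    prior_ab <- ab
    lp <- lc_log_posterior_cpp(init, counts, prior_ab)
    if (is.finite(lp)) return(init)
  }
  stop("Could not find initial values with finite log posterior.",
       call. = FALSE)
}

#' @export
print.lc_fit <- function(x, ...) {
  s <- x$schedule
  cat(sprintf(
    "Latent class model fit: %d chains, burn-in %d, thin %d, %d kept/chain\n",
    s$chains, s$burn_in, s$thin, s$n_keep))
  print(summarize_posterior(x), n = 12)
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor from the between- and within-chain
#' variances of the retained iterates:
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the chain means (times
#' n).  Values near 1 indicate convergence.  Parameters with zero
#' within-chain variance (stuck or fixed) are flagged with `NA` and a
#' warning; zero between-chain variance (e.g. duplicated chains) is flagged
#' as degenerate with a warning but still returns the statistic.
#'
#' @param fit An `lc_fit` object, or a list of equal-length numeric
#'   matrices/vectors (one per chain).
#' @return A tibble with columns `term` and `rhat`.
#' @export
gelman_rubin <- function(fit) {
  mats <- chains_as_matrices(fit)
  if (length(mats) < 2L) {
    stop("Gelman-Rubin requires at least 2 chains.", call. = FALSE)
  }
  n <- nrow(mats[[1]])
  if (n < 10L) stop("Chains must have length >= 10.", call. = FALSE)
  terms <- colnames(mats[[1]])
  rhat <- vapply(seq_along(terms), function(j) {
    ch <- vapply(mats, function(m) m[, j], numeric(n))
    W <- mean(apply(ch, 2, stats::var))
    B <- n * stats::var(colMeans(ch))
    if (W == 0) {
      warning("Zero within-chain variance for ", terms[j],
              "; Gelman-Rubin undefined.", call. = FALSE)
      return(NA_real_)
    }
    if (B == 0) {
      warning("Zero between-chain variance for ", terms[j],
              "; chains look degenerate (identical streams?).",
              call. = FALSE)
    }
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  tibble::tibble(term = terms, rhat = rhat)
}

chains_as_matrices <- function(fit) {
  if (inherits(fit, "lc_fit")) {
    free <- free_params(fit)
    return(lapply(seq_len(dim(fit$draws)[3]), function(ch) {
      matrix(fit$draws[, free, ch], ncol = length(free),
             dimnames = list(NULL, free))
    }))
  }
  if (is.list(fit)) {
    return(lapply(fit, function(m) {
      if (is.null(dim(m))) m <- matrix(m, ncol = 1,
                                       dimnames = list(NULL, "x"))
      m
    }))
  }
  stop("`fit` must be an lc_fit or a list of chains.", call. = FALSE)
}

free_params <- function(fit) {
  setdiff(lc_param_names, names(fit$fixed))
}

#' Posterior summary
#'
#' Pools the retained iterates of all chains and reports, per free
#' parameter, the posterior median, the central 95% probability interval
#' (2.5th and 97.5th percentiles, linear interpolation between order
#' statistics) and the Gelman-Rubin statistic.
#'
#' @param fit An `lc_fit` object.
#' @param conf.level Probability mass of the interval (default 0.95).
#' @return A tibble with columns `term`, `median`, `lower`, `upper`,
#'   `rhat`.
#' @export
summarize_posterior <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "lc_fit"))
  free <- free_params(fit)
  a <- (1 - conf.level) / 2
  qs <- apply(fit$draws[, free, , drop = FALSE], 2, function(x) {
    stats::quantile(c(x), probs = c(a, 0.5, 1 - a), names = FALSE, type = 7)
  })
  rh <- if (dim(fit$draws)[3] >= 2) gelman_rubin(fit) else
    tibble::tibble(term = free, rhat = NA_real_)
  tibble::tibble(
    term = free,
    median = unname(qs[2, ]),
    lower = unname(qs[1, ]),
    upper = unname(qs[3, ])
  ) |> dplyr::left_join(rh, by = "term")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a latent class fit
#'
#' @param x An `lc_fit` object.
#' @param conf.level Interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior median),
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.lc_fit <- function(x, conf.level = 0.95, ...) {
  summarize_posterior(x, conf.level) |>
    dplyr::rename(estimate = "median", conf.low = "lower",
                  conf.high = "upper")
}

#' One-row fit summary of a latent class fit
#'
#' @param x An `lc_fit` object.
#' @param ... Unused.
#' @return A tibble with the schedule, the worst Gelman-Rubin statistic
#'   across parameters and the mean Metropolis acceptance rate.
#' @export
glance.lc_fit <- function(x, ...) {
  free <- free_params(x)
  rh <- if (x$schedule$chains >= 2) {
    suppressWarnings(max(gelman_rubin(x)$rhat, na.rm = TRUE))
  } else NA_real_
  tibble::tibble(
    n_chains = x$schedule$chains,
    burn_in = x$schedule$burn_in,
    thin = x$schedule$thin,
    n_keep = x$schedule$n_keep,
    max_rhat = rh,
    mean_acceptance = mean(x$acceptance[free, ])
  )
}

#' Trace plots for a latent class fit
#'
#' @param object An `lc_fit` object.
#' @param ... Unused.
#' @return A ggplot with one facet per free parameter, retained iterates
#'   coloured by chain.
#' @export
autoplot.lc_fit <- function(object, ...) {
  free <- free_params(object)
  df <- purrr::map_dfr(seq_len(object$schedule$chains), function(ch) {
    m <- object$draws[, free, ch, drop = FALSE]
    tibble::tibble(
      iteration = rep(seq_len(nrow(m)), times = length(free)),
      term = rep(free, each = nrow(m)),
      value = c(m),
      chain = factor(ch)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "retained iterate", y = NULL,
                  title = "Posterior trace plots")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
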