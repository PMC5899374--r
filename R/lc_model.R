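#' Admissible range of a conditional covariance
#'
#' Two binary tests with conditional positivity probabilities `p` and `q`
#' (both sensitivities, or both specificities) can only exhibit a pairwise
#' covariance for which all four joint cell probabilities remain
#' non-negative: `lower = max(-p*q, -(1-p)*(1-q))` and
#' `upper = min(p*(1-q), (1-p)*q)`.  Zero (conditional independence) is
#' always admissible for interior `p`, `q`.
#'
#' @param p,q Probabilities strictly inside (0, 1); vectorised.
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' cov_bounds(0.5, 0.5)
#' @export
cov_bounds <- function(p, q) {
  if (any(!is.finite(p)) || any(!is.finite(q)) ||
      any(p <= 0) || any(p >= 1) || any(q <= 0) || any(q >= 1)) {
    stop("`p` and `q` must lie strictly inside (0, 1).", call. = FALSE)
  }
  tibble::tibble(
    lower = pmax(-p * q, -(1 - p) * (1 - q)),
    upper = pmin(p * (1 - q), (1 - p) * q)
  )
}

#' Latent class model parameters
#'
#' Parameter vector of the three-test (sucrose 45 min, sucrose 90 min,
#' gastroscopy), two-population (pre-/post-weaning) Hui-Walter latent class
#' model.  The two sucrose tests may be conditionally dependent: `cov_se`
#' is their covariance given disease, `cov_sp` given no disease, each
#' constrained to the admissible range of [cov_bounds()].  Gastroscopy is
#' conditionally independent of the sucrose tests given the latent state.
#' The constraint `se3 + sp3 > 1` anchors the latent class to "disease"
#' (gastroscopy is better than chance) and prevents label switching.
#'
#' @param pi1,pi2 Prevalence in the pre- and post-weaning populations.
#' @param se1,sp1 Sensitivity/specificity of sucrose at 45 min.
#' @param se2,sp2 Sensitivity/specificity of sucrose at 90 min.
#' @param se3,sp3 Sensitivity/specificity of gastroscopy.
#' @param cov_se,cov_sp Conditional covariances of the two sucrose tests
#'   given diseased / non-diseased status.
#' @return An object of class `lc_parameters` (a named list of the ten
#'   values).
#' @export
lc_parameters <- function(pi1, pi2, se1, sp1, se2, sp2, se3, sp3,
                          cov_se = 0, cov_sp = 0) {
  params <- structure(
    list(pi1 = pi1, pi2 = pi2, se1 = se1, sp1 = sp1, se2 = se2, sp2 = sp2,
         se3 = se3, sp3 = sp3, cov_se = cov_se, cov_sp = cov_sp),
    class = "lc_parameters"
  )
  validate_lc_parameters(params)
}

lc_param_names <- c("pi1", "pi2", "se1", "sp1", "se2", "sp2",
                    "se3", "sp3", "cov_se", "cov_sp")

validate_lc_parameters <- function(params) {
  if (!inherits(params, "lc_parameters")) {
    if (is.list(params) && all(lc_param_names %in% names(params))) {
      params <- structure(params[lc_param_names], class = "lc_parameters")
    } else {
      stop("`params` must be an lc_parameters object.", call. = FALSE)
    }
  }
  v <- unlist(params[lc_param_names])
  if (any(!is.finite(v))) {
    stop("All latent class parameters must be finite.", call. = FALSE)
  }
  probs <- v[1:8]
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("Prevalences and test accuracies must lie strictly inside (0, 1).",
         call. = FALSE)
  }
  bse <- cov_bounds(params$se1, params$se2)
  bsp <- cov_bounds(params$sp1, params$sp2)
  if (params$cov_se < bse$lower || params$cov_se > bse$upper) {
    stop(sprintf("`cov_se` = %.4f outside admissible range [%.4f, %.4f].",
                 params$cov_se, bse$lower, bse$upper), call. = FALSE)
  }
  if (params$cov_sp < bsp$lower || params$cov_sp > bsp$upper) {
    stop(sprintf("`cov_sp` = %.4f outside admissible range [%.4f, %.4f].",
                 params$cov_sp, bsp$lower, bsp$upper), call. = FALSE)
  }
  if (params$se3 + params$sp3 <= 1) {
    stop("Gastroscopy must be better than chance: se3 + sp3 > 1.",
         call. = FALSE)
  }
  params
}

#' @export
print.lc_parameters <- function(x, ...) {
  cat("Latent class parameters (3 tests, 2 populations):\n")
  print(unlist(x[lc_param_names]))
  invisible(x)
}

# 2 x 8 matrix of cell probabilities, rows pre/post, columns in
# lexicographic (t1, t2, t3) order with t1 most significant.
cell_prob_matrix <- function(params) {
  g <- pattern_grid()
  cell_row <- function(pi) {
    with(params, {
      dlt <- ifelse(g$t1 == g$t2, 1, -1)
      dis <- (se1^g$t1 * (1 - se1)^(1 - g$t1) *
                se2^g$t2 * (1 - se2)^(1 - g$t2) + dlt * cov_se) *
        se3^g$t3 * (1 - se3)^(1 - g$t3)
      nod <- ((1 - sp1)^g$t1 * sp1^(1 - g$t1) *
                (1 - sp2)^g$t2 * sp2^(1 - g$t2) + dlt * cov_sp) *
        (1 - sp3)^g$t3 * sp3^(1 - g$t3)
      pi * dis + (1 - pi) * nod
    })
  }
  m <- rbind(pre = cell_row(params$pi1), post = cell_row(params$pi2))
  colnames(m) <- pattern_labels()
  m
}

pattern_labels <- function() {
  g <- pattern_grid()
  sprintf("%d%d%d", g$t1, g$t2, g$t3)
}

#' Test-pattern probabilities under the latent class model
#'
#' For each population, the probability of each of the 8 joint outcomes of
#' (sucrose 45, sucrose 90, gastroscopy).  Within each latent class the two
#' sucrose tests have joint probabilities equal to the product of their
#' marginals plus/minus the conditional covariance (added on the concordant
#' patterns, subtracted on the discordant ones); gastroscopy then enters
#' independently given the latent state.  Each population's 8 cells sum
#' to 1.
#'
#' @param params An [lc_parameters()] object.
#' @return A 16-row tibble with columns `population`, `t1`, `t2`, `t3`,
#'   `prob`.
#' @export
cell_probabilities <- function(params) {
  params <- validate_lc_parameters(params)
  m <- cell_prob_matrix(params)
  g <- pattern_grid()
  tibble::tibble(
    population = rep(c("pre", "post"), each = 8L),
    t1 = rep(g$t1, 2L), t2 = rep(g$t2, 2L), t3 = rep(g$t3, 2L),
    prob = unname(c(m["pre", ], m["post", ]))
  )
}

# Coerce an lc_counts tibble (or compatible data frame) to the internal
# 2 x 8 matrix representation.
counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(identical(dim(counts), c(2L, 8L)))
    m <- counts
    rownames(m) <- c("pre", "post")
    return(m)
  }
  if (!is.data.frame(counts) ||
      !all(c("population", "t1", "t2", "t3", "count") %in% names(counts))) {
    stop("`counts` must have columns population, t1, t2, t3, count.",
         call. = FALSE)
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  if (!all(counts$population %in% c("pre", "post"))) {
    stop("`population` must be \"pre\" or \"post\".", call. = FALSE)
  }
  m <- matrix(0, 2, 8, dimnames = list(c("pre", "post"), pattern_labels()))
  idx <- 4L * counts$t1 + 2L * counts$t2 + counts$t3 + 1L
  for (i in seq_len(nrow(counts))) {
    m[counts$population[i], idx[i]] <- m[counts$population[i], idx[i]] +
      counts$count[i]
  }
  m
}

#' Cross-classify a cohort into latent class model counts
#'
#' Dichotomises the two sucrose measurements at `cutoff` (positive when
#' concentration >= cutoff) and tabulates the joint
#' (sucrose 45, sucrose 90, gastroscopy) outcome per occasion, producing
#' the sufficient statistic of the latent class model.
#'
#' @param data A foal-occasion cohort (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @param lesion Gastroscopy outcome column to use as the third test:
#'   `"gl"`, `"gdl"`, `"sql"` or `"csl"`.
#' @param cutoff Sucrose positivity cutoff in umol/L (default 24).
#' @return An `lc_counts` tibble (16 rows; see
#'   [simulate_crossclassified()]).
#' @export
cross_classify <- function(data, lesion = "gl", cutoff = 24) {
  lesion <- match.arg(lesion, c("gl", "gdl", "sql", "csl"))
  t1 <- dichotomize(data$sucrose45, cutoff)
  t2 <- dichotomize(data$sucrose90, cutoff)
  t3 <- as.integer(data[[lesion]])
  pop <- as.character(data$occasion)
  g <- pattern_grid()
  out <- tibble::tibble(
    population = rep(c("pre", "post"), each = 8L),
    t1 = rep(g$t1, 2L), t2 = rep(g$t2, 2L), t3 = rep(g$t3, 2L)
  )
  idx <- 4L * t1 + 2L * t2 + t3 + 1L
  out$count <- c(
    tabulate(idx[pop == "pre"], nbins = 8L),
    tabulate(idx[pop == "post"], nbins = 8L)
  )
  class(out) <- c("lc_counts", class(out))
  out
}

#' Multinomial log likelihood of cross-classified counts
#'
#' `sum(n * log(p))` over the 16 cells (up to the multinomial coefficient,
#' which does not depend on the parameters).  Returns `-Inf` when a cell
#' with positive count has zero probability; empty counts give 0.
#'
#' @param params An [lc_parameters()] object.
#' @param counts An `lc_counts` tibble or 2 x 8 matrix.
#' @return A scalar log likelihood.
#' @export
log_likelihood <- function(params, counts) {
  params <- validate_lc_parameters(params)
  n <- counts_matrix(counts)
  p <- cell_prob_matrix(params)
  pos <- n > 0
  if (!any(pos)) return(0)
  if (any(p[pos] <= 0)) return(-Inf)
  sum(n[pos] * log(p[pos]))
}

#' Log posterior density of the latent class model
#'
#' Adds to [log_likelihood()] the log Beta prior densities of the eight
#' probability parameters and uniform priors for the two conditional
#' covariances over their admissible ranges ([cov_bounds()] evaluated at
#' the current sensitivities/specificities).  Returns `-Inf` outside the
#' admissible region or when gastroscopy is not better than chance
#' (`se3 + sp3 <= 1`).
#'
#' @inheritParams log_likelihood
#' @param priors A prior set (see [egus_priors()]).
#' @return A scalar log posterior density (unnormalised).
#' @export
log_posterior <- function(params, counts, priors = egus_priors()) {
  validate_prior_set(priors)
  theta <- unlist(params[lc_param_names])
  n <- counts_matrix(counts)
  ab <- prior_ab_matrix(priors)
  lc_log_posterior_cpp(theta, n, ab)
}

# prior shapes in sampler order: pi1, pi2, se1, sp1, se2, sp2, se3, sp3
prior_ab_matrix <- function(priors) {
  ord <- c("prev_pre", "prev_post", "se_s45", "sp_s45",
           "se_s90", "sp_s90", "se_endo", "sp_endo")
  i <- match(ord, priors$parameter)
  cbind(alpha = priors$alpha[i], beta = priors$beta[i])
}
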