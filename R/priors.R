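#' Construct a Beta prior
#'
#' Beta(alpha, beta) distributions encode prior knowledge about probabilities
#' (prevalence, sensitivity, specificity) in the latent class analysis.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_prior`: a list with elements `alpha` and
#'   `beta`.
#' @examples
#' beta_prior(2, 8)
#' @export
beta_prior <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1L ||
      length(beta) != 1L || !is.finite(alpha) || !is.finite(beta) ||
      alpha <= 0 || beta <= 0) {
    stop("`alpha` and `beta` must be finite positive scalars.", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior\n", x$alpha, x$beta))
  invisible(x)
}

#' Summarise a Beta prior
#'
#' Computes the mean, median and a central equal-tailed probability interval
#' of a Beta distribution.  Quantiles are obtained by numerical inversion of
#' the regularised incomplete beta function ([stats::qbeta()], absolute
#' tolerance well below 1e-6).  The central interval with mass `mass` runs
#' from the (1 - mass)/2 to the 1 - (1 - mass)/2 quantile.
#'
#' @param prior A [beta_prior()], or a single positive `alpha` when `beta`
#'   is also given.
#' @param mass Probability mass of the central interval, in (0, 1).
#'   Default 0.90.
#' @param beta Optional second shape parameter, so
#'   `beta_summary(2, beta = 8)` works without constructing a prior first.
#' @return A one-row tibble with columns `alpha`, `beta`, `mean`, `median`,
#'   `lower`, `upper`, `mass`.
#' @examples
#' beta_summary(beta_prior(6, 4))
#' @export
beta_summary <- function(prior, mass = 0.90, beta = NULL) {
  if (!inherits(prior, "beta_prior")) {
    prior <- beta_prior(prior, beta)
  }
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) ||
      mass <= 0 || mass >= 1) {
    stop("`mass` must be a single probability strictly inside (0, 1).",
         call. = FALSE)
  }
  a <- prior$alpha
  b <- prior$beta
  tail <- (1 - mass) / 2
  tibble::tibble(
    alpha  = a,
    beta   = b,
    mean   = a / (a + b),
    median = stats::qbeta(0.5, a, b),
    lower  = stats::qbeta(tail, a, b),
    upper  = stats::qbeta(1 - tail, a, b),
    mass   = mass
  )
}

# Round half away from zero at `digits` decimals; base round() rounds half to
# even, which disagrees with the conventional display of e.g. 0.125 -> 0.13.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Elicited priors for the foal gastric ulcer latent class model
#'
#' The default prior set for the three-test, two-population analysis:
#' mildly informative Beta priors on pre- and post-weaning prevalence and on
#' gastroscopy sensitivity/specificity, and uniform Beta(1, 1) priors for
#' both sucrose tests (no prior accuracy information is assumed for the
#' screening test under evaluation).
#'
#' @return An object of class `prior_set`: a tibble with columns
#'   `parameter`, `alpha` and `beta`, one row per model parameter
#'   (`prev_pre`, `prev_post`, `se_endo`, `sp_endo`, `se_s45`, `sp_s45`,
#'   `se_s90`, `sp_s90`).
#' @seealso [prior_table()] for the summary analogue of the elicitation
#'   table.
#' @export
egus_priors <- function() {
  out <- tibble::tibble(
    parameter = c("prev_pre", "prev_post", "se_endo", "sp_endo",
                  "se_s45", "sp_s45", "se_s90", "sp_s90"),
    alpha = c(2, 6, 8, 99, 1, 1, 1, 1),
    beta  = c(8, 4, 2, 1, 1, 1, 1, 1)
  )
  class(out) <- c("prior_set", class(out))
  out
}

prior_set_params <- c("prev_pre", "prev_post", "se_endo", "sp_endo",
                      "se_s45", "sp_s45", "se_s90", "sp_s90")

validate_prior_set <- function(priors) {
  if (!is.data.frame(priors) ||
      !all(c("parameter", "alpha", "beta") %in% names(priors))) {
    stop("`priors` must be a data frame with columns parameter, alpha, beta.",
         call. = FALSE)
  }
  missing <- setdiff(prior_set_params, priors$parameter)
  if (length(missing)) {
    stop("Prior set is missing parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(priors$alpha)) || any(!is.finite(priors$beta)) ||
      any(priors$alpha <= 0) || any(priors$beta <= 0)) {
    stop("All prior shape parameters must be finite and positive.",
         call. = FALSE)
  }
  invisible(priors)
}

#' Prior summary table
#'
#' Summarises each prior in a prior set (mean, median, central interval),
#' both at full precision and rounded for display.
#'
#' @param priors A prior set as returned by [egus_priors()].
#' @param mass Central interval mass (default 0.90).
#' @param digits Decimals for the rounded display columns (default 3).
#' @return A tibble with one row per parameter: `parameter`, `alpha`,
#'   `beta`, full-precision `mean`, `median`, `lower`, `upper`, and rounded
#'   display columns suffixed `_r`.
#' @examples
#' prior_table()
#' @export
prior_table <- function(priors = egus_priors(), mass = 0.90, digits = 3) {
  validate_prior_set(priors)
  summ <- purrr::map2(priors$alpha, priors$beta,
                      function(a, b) beta_summary(beta_prior(a, b), mass))
  summ <- dplyr::bind_rows(summ)
  dplyr::bind_cols(priors["parameter"], summ) |>
    dplyr::mutate(
      mean_r   = round_half_up(.data$mean, 2),
      median_r = round_half_up(.data$median, 2),
      lower_r  = round_half_up(.data$lower, digits),
      upper_r  = round_half_up(.data$upper, digits)
    )
}
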