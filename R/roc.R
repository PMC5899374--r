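#' Dichotomise sucrose concentrations at a cutoff
#'
#' A concentration is test-positive when it is greater than or equal to the
#' cutoff.  With the study's 24 umol/L cutoff a foal measuring 35.4 umol/L
#' is classified positive.
#'
#' @param value Concentrations in umol/L; must be strictly positive.
#' @param cutoff Positivity cutoff in umol/L (default 24).
#' @return Integer vector of 0/1 test results.
#' @examples
#' dichotomize(c(35.4, 10), 24)
#' @export
dichotomize <- function(value, cutoff = 24) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("Concentrations must be finite and strictly positive.",
         call. = FALSE)
  }
  as.integer(value >= cutoff)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to relate the 45-
#' and 90-minute sucrose measurements.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length.", call. = FALSE)
  }
  if (length(x) < 3L) stop("Need at least 3 observations.", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("Spearman's rho is undefined for a constant vector.",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("`labels` must be 0/1.", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("Both diseased and non-diseased subjects are required.",
         call. = FALSE)
  }
  as.integer(labels)
}

#' Empirical ROC curve
#'
#' One operating point per distinct observed concentration (positivity when
#' value >= threshold) plus the (0, 0) endpoint at threshold `Inf`; the
#' (1, 1) endpoint is reached at the smallest observed value.
#'
#' @param values Test measurements (concentrations).
#' @param labels 0/1 disease status (both classes required).
#' @return A tibble of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, `fpr` (= 1 - specificity), ordered by
#'   decreasing threshold.
#' @examples
#' empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
empirical_roc <- function(values, labels) {
  labels <- check_labels(labels)
  if (length(values) != length(labels)) {
    stop("`values` and `labels` must have the same length.", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  se <- vapply(thr, function(t) sum(values >= t & labels == 1L) / n_pos,
               numeric(1))
  fp <- vapply(thr, function(t) sum(values >= t & labels == 0L) / n_neg,
               numeric(1))
  out <- tibble::tibble(threshold = thr, sensitivity = se,
                        specificity = 1 - fp, fpr = fp)
  class(out) <- c("roc_curve", class(out))
  out
}

#' Plot an ROC curve
#'
#' @param object A `roc_curve` from [empirical_roc()].
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity with the chance
#'   diagonal.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity")
}

#' Mann-Whitney AUC
#'
#' Area under the empirical ROC curve via the Mann-Whitney estimator: the
#' fraction of (diseased, non-diseased) pairs in which the diseased subject
#' has the higher value, ties counted one half.
#'
#' @inheritParams empirical_roc
#' @return AUC in \[0, 1\].
#' @examples
#' auc_point(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
auc_point <- function(values, labels) {
  labels <- check_labels(labels)
  r <- rank(values)  # average ranks handle ties as 1/2
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden's index
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @return `se + sp - 1`.
#' @export
youden <- function(se, sp) {
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    stop("`se` and `sp` must be probabilities.", call. = FALSE)
  }
  se + sp - 1
}

#' Weighted Youden's index
#'
#' Variant weighting sensitivity twice as important as specificity:
#' `1.33 * se + 0.67 * sp - 1`, favouring cutoffs suitable for a screening
#' test where missed cases are costlier than false alarms.
#'
#' @inheritParams youden
#' @return The weighted index.
#' @export
weighted_youden <- function(se, sp) {
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    stop("`se` and `sp` must be probabilities.", call. = FALSE)
  }
  1.33 * se + 0.67 * sp - 1
}

#' Select an optimal cutoff from an ROC curve
#'
#' Maximises the chosen index over the curve's finite thresholds.  Ties are
#' broken toward the lower threshold (higher sensitivity).
#' `"manual_max_se"` instead returns the largest threshold that achieves
#' the maximal sensitivity among operating points with specificity > 0,
#' mimicking manual selection of a practical screening threshold.
#'
#' @param roc A `roc_curve` from [empirical_roc()].
#' @param method `"youden"`, `"weighted_youden"` or `"manual_max_se"`.
#' @return A one-row tibble: `method`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `weighted_youden`.
#' @export
select_cutoff <- function(roc,
                          method = c("youden", "weighted_youden",
                                     "manual_max_se")) {
  method <- match.arg(method)
  pts <- roc[is.finite(roc$threshold), ]
  if (nrow(pts) < 1L ||
      (length(unique(pts$sensitivity)) < 2L &&
       length(unique(pts$specificity)) < 2L)) {
    stop("ROC curve is degenerate; cannot select a cutoff.", call. = FALSE)
  }
  if (method == "manual_max_se") {
    cand <- pts[pts$specificity > 0, ]
    if (nrow(cand) == 0L) {
      stop("No operating point has positive specificity.", call. = FALSE)
    }
    cand <- cand[cand$sensitivity == max(cand$sensitivity), ]
    best <- cand[which.max(cand$threshold), ]
  } else {
    idx <- if (method == "youden") {
      youden(pts$sensitivity, pts$specificity)
    } else {
      weighted_youden(pts$sensitivity, pts$specificity)
    }
    # ties broken toward the lower threshold: scan in decreasing-threshold
    # order and keep the LAST maximum
    best_i <- max(which(idx == max(idx)))
    best <- pts[best_i, ]
  }
  tibble::tibble(
    method = method,
    cutoff = best$threshold,
    sensitivity = best$sensitivity,
    specificity = best$specificity,
    youden = youden(best$sensitivity, best$specificity),
    weighted_youden = weighted_youden(best$sensitivity, best$specificity)
  )
}

#' Percent agreement and Cohen's kappa
#'
#' Chance-corrected agreement between two raters' binary calls:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and expected
#' agreement `pe` from the raters' marginal proportions.
#'
#' @param r1,r2 Equal-length 0/1 vectors (length >= 2).
#' @return A one-row tibble with `percent_agreement` and `kappa`.  When
#'   both raters are constant (`pe = 1`), kappa is undefined and returned
#'   as `NA` with a warning.
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2) || length(r1) < 2L) {
    stop("`r1` and `r2` must have equal length >= 2.", call. = FALSE)
  }
  if (!all(r1 %in% c(0, 1)) || !all(r2 %in% c(0, 1))) {
    stop("Ratings must be 0/1.", call. = FALSE)
  }
  po <- mean(r1 == r2)
  p1 <- mean(r1 == 1)
  p2 <- mean(r2 == 1)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  kappa <- if (pe >= 1) {
    warning("Both raters are constant; kappa is undefined.", call. = FALSE)
    NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  tibble::tibble(percent_agreement = po, kappa = kappa)
}
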