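#' Run the full diagnostic-accuracy study analysis
#'
#' Orchestrates, per lesion type: gold-standard prevalence pre and post
#' weaning with cluster-bootstrap intervals, the exact McNemar pre/post
#' comparison, ROC curves and cluster-bootstrap AUCs for the 45- and
#' 90-minute sucrose measurements, the paired bootstrap comparison of the
#' two AUCs, Youden-selected cutoffs, sensitivity/specificity at the
#' configured cutoff, and the Bayesian latent class fit on the
#' cross-classified counts; plus the 45/90 Spearman correlation and the
#' incidence rate of new gastric lesion cases.  Every stage draws its seed
#' from the master seed by a fixed counter scheme recorded in the report's
#' metadata, so the whole analysis is reproducible from one integer.
#'
#' Stages that fail (e.g. paired analyses on a single-occasion dataset)
#' are reported as error messages in the affected table; the remaining
#' stages still run.
#'
#' @param data A foal-occasion cohort (see [read_cohort()] /
#'   [simulate_cohort()]).
#' @param cutoff Sucrose positivity cutoff in umol/L (default 24).
#' @param n_boot Bootstrap replicates per frequentist stage (default
#'   2000).
#' @param lesions Lesion types to analyse (default all four).
#' @param mcmc_profile `"desk"` or `"paper"` schedule for the latent class
#'   fits (see [mcmc_profile()]).
#' @param priors Prior set for the latent class model.
#' @param weeks_between Weeks between samplings for the incidence rate.
#' @param seed Master seed.
#' @return An object of class `study_report`: a list of tibbles
#'   (`prevalence`, `prevalence_test`, `auc`, `auc_comparison`,
#'   `cutoff_selection`, `accuracy`, `bayes`, `correlation`, `incidence`,
#'   `priors`, `errors`) plus `meta`.
#' @export
run_study <- function(data, cutoff = 24, n_boot = 2000L,
                      lesions = c("gl", "gdl", "sql", "csl"),
                      mcmc_profile = "desk", priors = egus_priors(),
                      weeks_between = 3, seed = 1L) {
  check_cohort(data)
  lesions <- match.arg(lesions, lesion_cols, several.ok = TRUE)
  sched <- mcmc_profile(mcmc_profile)

  # counter-based fan-out: stage k uses seed * 1000 + k (mod 2^31 - 1)
  stage_counter <- new.env(parent = emptyenv())
  stage_counter$k <- 0L
  stage_counter$log <- character()
  stage_seed <- function(label) {
    stage_counter$k <- stage_counter$k + 1L
    s <- as.integer((as.double(seed) * 1000 + stage_counter$k) %%
                      (2^31 - 1))
    stage_counter$log <- c(stage_counter$log,
                           sprintf("%s: %d", label, s))
    s
  }
  errors <- list()
  try_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      errors[[label]] <<- conditionMessage(e)
      NULL
    })
  }

  corr <- try_stage("correlation", tibble::tibble(
    spearman_rho = spearman_rho(data$sucrose45, data$sucrose90),
    n = nrow(data)
  ))

  prev <- list(); prev_test <- list(); aucs <- list(); auc_cmp <- list()
  cuts <- list(); acc <- list(); bayes <- list(); incid <- list()
  for (les in lesions) {
    for (occ in c("pre", "post")) {
      prev[[paste(les, occ)]] <- try_stage(
        paste0("prevalence_", les, "_", occ),
        prevalence(data, les, occ, n_boot,
                   seed = stage_seed(paste0("prevalence_", les, "_", occ))))
    }
    prev_test[[les]] <- try_stage(paste0("mcnemar_", les),
                                  paired_prevalence_test(data, les))
    incid[[les]] <- try_stage(paste0("incidence_", les),
                              incidence_rate(data, les, weeks_between))
    for (tm in c(45, 90)) {
      aucs[[paste(les, tm)]] <- try_stage(
        paste0("auc_", les, "_", tm),
        cluster_bootstrap_auc(data, les, tm, n_boot,
                              seed = stage_seed(paste0("auc_", les, "_",
                                                       tm))))
      cuts[[paste(les, tm)]] <- try_stage(
        paste0("cutoff_", les, "_", tm), {
          roc <- empirical_roc(data[[sucrose_col(tm)]], data[[les]])
          dplyr::bind_cols(tibble::tibble(lesion = les,
                                          time = as.integer(tm)),
                           select_cutoff(roc, "youden"))
        })
      acc[[paste(les, tm)]] <- try_stage(
        paste0("accuracy_", les, "_", tm),
        se_sp_at_cutoff(data, les, tm, cutoff, n_boot,
                        seed = stage_seed(paste0("accuracy_", les, "_",
                                                 tm))))
    }
    auc_cmp[[les]] <- try_stage(
      paste0("auc_comparison_", les),
      compare_auc(data, les, n_boot,
                  seed = stage_seed(paste0("auc_comparison_", les))))
    bayes[[les]] <- try_stage(paste0("bayes_lc_", les), {
      counts <- cross_classify(data, les, cutoff)
      fit <- run_mcmc(counts, priors, chains = sched$chains,
                      burn_in = sched$burn_in, thin = sched$thin,
                      n_keep = sched$n_keep,
                      seed = stage_seed(paste0("bayes_lc_", les)))
      dplyr::bind_cols(tibble::tibble(lesion = les), tidy(fit))
    })
  }

  structure(list(
    prevalence = dplyr::bind_rows(prev),
    prevalence_test = dplyr::bind_rows(prev_test),
    auc = dplyr::bind_rows(aucs),
    auc_comparison = dplyr::bind_rows(auc_cmp),
    cutoff_selection = dplyr::bind_rows(cuts),
    accuracy = dplyr::bind_rows(acc),
    bayes = dplyr::bind_rows(bayes),
    correlation = corr,
    incidence = dplyr::bind_rows(incid),
    priors = prior_table(priors),
    errors = errors,
    meta = list(seed = as.integer(seed), cutoff = cutoff,
                n_boot = as.integer(n_boot), mcmc = sched,
                stage_seeds = stage_counter$log,
                package_version = as.character(
                  utils::packageVersion("sucroselc")))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Blood sucrose diagnostic accuracy study report\n")
  cat(sprintf("  master seed %d, cutoff %g umol/L, %d bootstrap replicates\n",
              x$meta$seed, x$meta$cutoff, x$meta$n_boot))
  if (!is.null(x$correlation)) {
    cat(sprintf("  Spearman rho (45 vs 90 min): %.3f\n",
                x$correlation$spearman_rho))
  }
  cat("\nPrevalence (gold standard):\n")
  print(x$prevalence)
  cat("\nAUC (cluster bootstrap):\n")
  print(x$auc)
  cat("\nAccuracy at cutoff (gold standard):\n")
  print(x$accuracy)
  cat("\nBayesian latent class estimates:\n")
  print(x$bayes, n = 40)
  if (length(x$errors)) {
    cat("\nStages with errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}

#' Tidy the tables of a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A long tibble binding the report's main tables with a `table`
#'   column.
#' @export
tidy.study_report <- function(x, ...) {
  tabs <- c("prevalence", "auc", "accuracy", "bayes")
  purrr::map_dfr(tabs, function(nm) {
    tb <- x[[nm]]
    if (is.null(tb) || nrow(tb) == 0L) return(NULL)
    num_cols <- names(tb)[vapply(tb, is.numeric, logical(1))]
    tb |>
      tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "quantity",
                          values_to = "value") |>
      dplyr::mutate(table = nm, .before = 1)
  })
}
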