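cohort_csv_cols <- c("foal_id", "occasion", "sucrose45_umol_l",
                     "sucrose90_umol_l", "gl", "gdl", "sql", "csl")

#' Write a foal cohort to CSV
#'
#' Columns: `foal_id`, `occasion` (`"pre"`/`"post"`), `sucrose45_umol_l`,
#' `sucrose90_umol_l`, `gl`, `gdl`, `sql`, `csl` (0/1) and, when present,
#' `latent_state`.
#'
#' @param data A foal-occasion cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  check_cohort(data)
  out <- data |>
    dplyr::rename(sucrose45_umol_l = "sucrose45",
                  sucrose90_umol_l = "sucrose90")
  keep <- c(cohort_csv_cols,
            if ("latent_state" %in% names(out)) "latent_state")
  readr::write_csv(out[keep], path)
  invisible(path)
}

#' Read and validate a foal cohort CSV
#'
#' Reads the CSV schema of [write_cohort()] and validates every record:
#' positive numeric concentrations, 0/1 lesion indicators, unique
#' (foal, occasion) pairs, at most two occasions per foal, and the subtype
#' implications (a glandular, squamous or clinically significant lesion
#' implies a gastric lesion).  Validation failures report the offending row
#' numbers.
#'
#' @param path Path to a cohort CSV.
#' @return A validated cohort tibble with columns `foal_id`, `occasion`,
#'   `sucrose45`, `sucrose90`, `gl`, `gdl`, `sql`, `csl`
#'   (and `latent_state` when present in the file).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("Could not parse CSV: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(raw) == 0L) stop("Cohort file is empty.", call. = FALSE)
  missing <- setdiff(cohort_csv_cols, names(raw))
  if (length(missing)) {
    stop("Missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- raw |>
    dplyr::rename(sucrose45 = "sucrose45_umol_l",
                  sucrose90 = "sucrose90_umol_l")

  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop("Invalid cohort file: ", what, " in row(s) ",
           paste(utils::head(which(cond), 10), collapse = ", "), ".",
           call. = FALSE)
    }
  }
  bad_row(!data$occasion %in% c("pre", "post"),
          "occasion must be \"pre\" or \"post\"")
  for (col in c("sucrose45", "sucrose90")) {
    bad_row(!is.numeric(data[[col]]) | !is.finite(data[[col]]) |
              data[[col]] <= 0,
            paste0("non-positive or non-numeric ", col))
  }
  for (col in c(lesion_cols, intersect("latent_state", names(data)))) {
    bad_row(!data[[col]] %in% c(0, 1), paste0(col, " must be 0/1"))
  }
  bad_row((data$gdl == 1 | data$sql == 1) & data$gl == 0,
          "subtype lesion recorded without a gastric lesion (gl = 0)")
  bad_row(data$csl == 1 & data$gl == 0,
          "clinically significant lesion without a gastric lesion")
  dup <- duplicated(data[c("foal_id", "occasion")])
  bad_row(dup, "duplicate (foal_id, occasion) pair")

  data |> dplyr::mutate(dplyr::across(dplyr::all_of(lesion_cols),
                                      as.integer))
}

#' Write a simulation configuration to a key-value file
#'
#' Plain-text `key = value` representation of a [sim_config()]; pair
#' fields are comma-separated.
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- function(x) paste(format(x, digits = 15, trim = TRUE),
                           collapse = ", ")
  lines <- c(
    paste("n_foals =", config$n_foals),
    paste("prev_pre =", fmt(config$prev_pre)),
    paste("prev_post =", fmt(config$prev_post)),
    paste("mean_sd_normal_45 =", fmt(config$mean_sd_normal_45)),
    paste("mean_sd_normal_90 =", fmt(config$mean_sd_normal_90)),
    paste("mean_sd_diseased_45 =", fmt(config$mean_sd_diseased_45)),
    paste("mean_sd_diseased_90 =", fmt(config$mean_sd_diseased_90)),
    paste("log_corr =", fmt(config$log_corr)),
    paste("endo_se =", fmt(config$endo_se)),
    paste("endo_sp =", fmt(config$endo_sp)),
    paste("subtype_probs =", fmt(config$subtype_probs)),
    if (!is.null(config$seed)) paste("seed =", config$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation configuration from a key-value file
#'
#' @param path Path to a file written by [write_sim_config()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("Malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- lapply(kv, function(x) {
    as.numeric(trimws(strsplit(x[[2]], ",", fixed = TRUE)[[1]]))
  })
  names(vals) <- keys
  if ("subtype_probs" %in% keys) {
    names(vals$subtype_probs) <- c("gdl", "sql", "csl")
  }
  do.call(sim_config, vals)
}
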