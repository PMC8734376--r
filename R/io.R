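#' Read a survival-mediation dataset from delimited text
#'
#' Reads a CSV/TSV file (delimiter sniffed from the extension or the first
#' line; a header is required), maps columns, and applies the standard
#' cleaning: rows missing time, status or exposure are dropped with a
#' message; missing mediator cells are mean-imputed per column with a
#' message.
#'
#' @param path File path.
#' @inheritParams survmed_data
#' @param delim Field delimiter; `NULL` to sniff.
#' @return A `survmed_data` object.
#' @export
read_survmed <- function(path, time = "time", status = "status",
                         exposure = "exposure", covariates = NULL,
                         mediators = NULL, mediator_prefix = NULL,
                         delim = NULL) {
  if (!file.exists(path)) stop_bad_arg(sprintf("File '%s' not found.", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  nm <- names(df)
  need <- c(time, status, exposure)
  missing_cols <- setdiff(c(need, covariates), nm)
  if (length(missing_cols)) {
    stop_bad_arg(sprintf("Column(s) %s not found; candidates: %s.",
                         paste0("'", missing_cols, "'", collapse = ", "),
                         paste(utils::head(nm, 10), collapse = ", ")))
  }
  core_na <- !stats::complete.cases(df[need])
  if (any(core_na)) {
    inform(sprintf("dropped %d row(s) with missing time/status/exposure.",
                   sum(core_na)))
    df <- df[!core_na, , drop = FALSE]
  }
  if (is.null(mediators) && !is.null(mediator_prefix)) {
    mediators <- setdiff(grep(paste0("^", mediator_prefix), nm, value = TRUE),
                         c(need, covariates))
  }
  if (is.null(mediators) || !length(mediators)) {
    stop_bad_arg("No mediator columns identified; supply `mediators` or `mediator_prefix`.")
  }
  for (mc in mediators) {
    col <- df[[mc]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop_bad_arg(sprintf("Non-numeric mediator cell in column '%s' (row %s).",
                           mc, bad %||% "?"))
    }
    if (anyNA(col)) {
      inform(sprintf("mean-imputed %d missing value(s) in mediator '%s'.",
                     sum(is.na(col)), mc))
      df[[mc]][is.na(col)] <- mean(col, na.rm = TRUE)
    }
  }
  survmed_data(as.data.frame(df), time = time, status = status,
               exposure = exposure, covariates = covariates,
               mediators = mediators)
}

#' Write a survival-mediation dataset to delimited text
#'
#' @param data A `survmed_data` object.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_survmed <- function(data, path) {
  if (!inherits(data, "survmed_data")) stop_bad_arg("`data` must be a survmed_data object.")
  df <- as_tibble(data)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Write the result files of a mediation run
#'
#' Emits fixed-column TSVs (diffable across runs): the per-mediator record
#' table with the application-style columns (mediator, Est.IE, CI bounds,
#' P(BH), P(BY), SE, beta, alpha), the screening score table, the
#' cross-validation curve, and a JSON manifest (seed, package version,
#' configuration) sufficient to reproduce the run.
#'
#' @param result A [mediate_ahaz()] object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_mediation_results <- function(result, dir) {
  if (!inherits(result, "mediate_ahaz")) {
    stop_bad_arg("`result` must come from mediate_ahaz().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- result$records
  tab <- tibble(
    mediator = rec$mediator, est_ie = rec$ie_hat,
    ci_low = rec$ci_low, ci_high = rec$ci_high,
    p_bh = rec$p_bh, p_by = rec$p_by, se = rec$sobel_se,
    beta_hat = rec$beta_hat, alpha_hat = rec$alpha_hat,
    significant = rec$significant
  )
  readr::write_tsv(tab, file.path(dir, "mediation_records.tsv"))
  readr::write_tsv(as_tibble(result$screen)[c("mediator", "score", "rank", "selected")],
                   file.path(dir, "screening_scores.tsv"))
  readr::write_tsv(result$scad$cv_curve, file.path(dir, "cv_curve.tsv"))
  readr::write_tsv(as_tibble(result$decomposition),
                   file.path(dir, "effect_decomposition.tsv"))
  manifest <- list(
    package = "ahazmed",
    version = as.character(utils::packageVersion("ahazmed")),
    config = result$config,
    n = result$n, p = result$p,
    lambda_star = result$scad$lambda_star,
    n_selected = nrow(result$scad$selected),
    n_significant = sum(rec$significant)
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
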