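#' Assemble a survival-mediation dataset
#'
#' Bundles the per-subject pieces of a mediation analysis for survival data:
#' observed follow-up time \eqn{T_i = \min(D_i, C_i)}, event indicator
#' \eqn{\delta_i}, a scalar exposure \eqn{X_i}, a small set of covariates
#' \eqn{Z_i}, and a (typically very wide) mediator matrix \eqn{M} with one
#' column per candidate mediator, e.g. per CpG site.
#'
#' All downstream functions ([sis_screen()], [cv_ahaz_scad()],
#' [mediate_ahaz()], ...) accept either this object or a plain data frame
#' plus the same column-mapping arguments.
#'
#' @param data A data frame with one row per subject.
#' @param time,status,exposure Names of the follow-up time, event-indicator
#'   (0 = censored, 1 = event) and exposure columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty or `NULL`).
#' @param mediators Character vector of mediator column names, or `NULL` to
#'   use `mediator_prefix`.
#' @param mediator_prefix All columns whose name starts with this prefix are
#'   treated as mediators (convenient for methylation arrays, e.g. `"cg"`).
#'
#' @return An object of class `survmed_data`: a list with elements `time`,
#'   `status`, `exposure` (length-n vectors), `covariates` (n x q matrix),
#'   `mediators` (n x p matrix) and `mediator_names`.
#' @examples
#' df <- data.frame(
#'   time = c(1, 2, 3, 4, 5), status = c(1, 0, 1, 1, 0),
#'   smoke = c(0, 1, 1, 0, 1),
#'   cg1 = rnorm(5), cg2 = rnorm(5)
#' )
#' sd <- survmed_data(df, time = "time", status = "status",
#'                    exposure = "smoke", mediator_prefix = "cg")
#' sd
#' @export
survmed_data <- function(data, time = "time", status = "status",
                         exposure = "exposure", covariates = NULL,
                         mediators = NULL, mediator_prefix = NULL) {
  if (!is.data.frame(data)) stop_bad_arg("`data` must be a data frame.")
  nm <- names(data)
  need <- c(time, status, exposure, covariates, mediators)
  missing_cols <- setdiff(need, nm)
  if (length(missing_cols)) {
    stop_bad_arg(sprintf(
      "Column(s) %s not found; available columns include %s.",
      paste0("'", missing_cols, "'", collapse = ", "),
      paste0("'", utils::head(nm, 8), "'", collapse = ", ")
    ))
  }
  if (is.null(mediators)) {
    if (is.null(mediator_prefix)) {
      stop_bad_arg("Supply either `mediators` or `mediator_prefix`.")
    }
    mediators <- setdiff(grep(paste0("^", mediator_prefix), nm, value = TRUE),
                         c(time, status, exposure, covariates))
    if (!length(mediators)) {
      stop_bad_arg(sprintf("No columns match mediator prefix '%s'.", mediator_prefix))
    }
  }
  overlap <- intersect(c(time, status, exposure, covariates), mediators)
  if (length(overlap)) {
    stop_bad_arg(sprintf("Column(s) %s mapped both as mediator and as outcome/design: %s.",
                         "", paste(overlap, collapse = ", ")))
  }
  Z <- as.matrix(data[covariates %||% character()])
  storage.mode(Z) <- "double"
  M <- as.matrix(data[mediators])
  if (!is.numeric(M)) stop_bad_arg("Mediator columns must all be numeric.")
  storage.mode(M) <- "double"
  new_survmed_data(
    time = as.double(data[[time]]),
    status = as.double(data[[status]]),
    exposure = as.double(data[[exposure]]),
    covariates = Z,
    mediators = M,
    mediator_names = mediators
  )
}

#' Low-level constructor from components
#'
#' Used by [survmed_data()], the simulator and the readers; validates the
#' alignment invariants shared by every analysis entry point.
#'
#' @param time,status,exposure Length-n numeric vectors.
#' @param covariates n x q numeric matrix (q may be 0).
#' @param mediators n x p numeric matrix.
#' @param mediator_names Unique identifiers, length p.
#' @return A `survmed_data` object.
#' @export
new_survmed_data <- function(time, status, exposure,
                             covariates = matrix(0, length(time), 0),
                             mediators, mediator_names = colnames(mediators)) {
  n <- length(time)
  mediators <- as.matrix(mediators)
  covariates <- as.matrix(covariates)
  if (is.null(mediator_names)) {
    mediator_names <- paste0("M", seq_len(ncol(mediators)))
  }
  x <- structure(
    list(time = as.double(time), status = as.double(status),
         exposure = as.double(exposure), covariates = covariates,
         mediators = mediators, mediator_names = as.character(mediator_names)),
    class = "survmed_data"
  )
  validate_survmed_data(x)
}

validate_survmed_data <- function(x) {
  n <- length(x$time)
  if (length(x$status) != n || length(x$exposure) != n ||
      nrow(x$covariates) != n || nrow(x$mediators) != n) {
    stop_bad_arg("All components must share the same number of subjects.")
  }
  if (anyNA(x$time) || anyNA(x$status) || anyNA(x$exposure) ||
      anyNA(x$covariates) || anyNA(x$mediators)) {
    stop_bad_arg("Missing or NaN values are not allowed in a survmed_data object.")
  }
  if (any(x$time <= 0)) stop_bad_arg("All follow-up times must be positive.")
  if (!all(x$status %in% c(0, 1))) {
    stop_bad_arg("`status` must contain only 0 (censored) and 1 (event).")
  }
  if (sum(x$status) < 1) {
    abort("no observed failures: at least one event is required.",
          class = "ahazmed_no_events")
  }
  if (anyDuplicated(x$mediator_names)) {
    stop_bad_arg("Mediator names must be unique.")
  }
  if (length(x$mediator_names) != ncol(x$mediators)) {
    stop_bad_arg("`mediator_names` must have one entry per mediator column.")
  }
  x
}

#' Coerce to survmed_data
#' @param data A `survmed_data` object or data frame.
#' @param ... Column mapping passed to [survmed_data()] when `data` is a
#'   data frame.
#' @return A `survmed_data` object.
#' @export
as_survmed_data <- function(data, ...) {
  if (inherits(data, "survmed_data")) return(data)
  survmed_data(data, ...)
}

#' @export
print.survmed_data <- function(x, ...) {
  cat(sprintf(
    "<survmed_data> %d subjects, %d events (%.1f%% censored)\n",
    length(x$time), sum(x$status), 100 * mean(x$status == 0)
  ))
  cat(sprintf("  covariates: %d, mediators: %d (%s%s)\n",
              ncol(x$covariates), ncol(x$mediators),
              paste(utils::head(x$mediator_names, 3), collapse = ", "),
              if (ncol(x$mediators) > 3) ", ..." else ""))
  invisible(x)
}

#' @export
dim.survmed_data <- function(x) c(length(x$time), ncol(x$mediators))

#' Convert a survmed_data object back to a tibble
#'
#' One row per subject, with the mediator columns last; inverse of
#' [survmed_data()] up to column order.
#' @param x A `survmed_data` object.
#' @param ... Unused.
#' @method as_tibble survmed_data
#' @export
as_tibble.survmed_data <- function(x, ...) {
  out <- tibble(time = x$time, status = x$status, exposure = x$exposure)
  if (ncol(x$covariates)) {
    Z <- x$covariates
    colnames(Z) <- colnames(Z) %||% paste0("Z", seq_len(ncol(Z)))
    out <- dplyr::bind_cols(out, as_tibble(Z))
  }
  M <- x$mediators
  colnames(M) <- x$mediator_names
  dplyr::bind_cols(out, as_tibble(M))
}
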