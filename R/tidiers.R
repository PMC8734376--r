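#' Tidy an additive-hazards fit
#'
#' @param x An [ahaz_fit()] object.
#' @param conf_level Wald confidence level.
#' @param ... Unused.
#' @return A tibble: `term`, `role`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @method tidy ahaz_fit
#' @export
tidy.ahaz_fit <- function(x, conf_level = 0.95, ...) {
  z <- ifelse(x$std_errors > 0, x$estimates / x$std_errors, NA_real_)
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = names(x$estimates), role = x$roles,
    estimate = unname(x$estimates), std_error = unname(x$std_errors),
    statistic = unname(z), p_value = unname(2 * (1 - pnorm(abs(z)))),
    conf_low = unname(x$estimates - q * x$std_errors),
    conf_high = unname(x$estimates + q * x$std_errors)
  )
}

#' @rdname tidy.ahaz_fit
#' @method glance ahaz_fit
#' @export
glance.ahaz_fit <- function(x, ...) {
  tibble(n = x$statistics$n, n_events = x$statistics$n_events,
         n_terms = length(x$estimates))
}

#' Tidy a full mediation-procedure result
#'
#' @param x A [mediate_ahaz()] object.
#' @param ... Unused.
#' @return The per-mediator record tibble (see [refit_and_test()]).
#' @method tidy mediate_ahaz
#' @export
tidy.mediate_ahaz <- function(x, ...) {
  rec <- x$records
  for (a in c("refit", "gamma_hat", "gamma_se", "adjust")) attr(rec, a) <- NULL
  rec
}

#' @rdname tidy.mediate_ahaz
#' @method glance mediate_ahaz
#' @export
glance.mediate_ahaz <- function(x, ...) {
  dec <- x$decomposition
  tibble(
    n = x$n, p = x$p, d = x$config$d,
    n_selected = nrow(x$scad$selected),
    n_significant = sum(x$records$significant),
    lambda_star = x$scad$lambda_star,
    te = dec$te, de = dec$de, ie_total = dec$ie_total,
    te_marginal = dec$te_marginal
  )
}

#' @export
print.mediate_ahaz <- function(x, ...) {
  cat(sprintf("<mediate_ahaz> n = %d subjects, p = %d mediators\n", x$n, x$p))
  cat(sprintf("  screening kept d = %d; SCAD selected |S2| = %d; %d significant (%s-adjusted p < %g)\n",
              x$config$d, nrow(x$scad$selected), sum(x$records$significant),
              toupper(x$config$adjust), x$config$level))
  dec <- x$decomposition
  cat(sprintf("  TE = %.4f = DE %.4f + IE %.4f (contrast %g)\n",
              dec$te, dec$de, dec$ie_total, dec$exposure_contrast))
  if (nrow(x$records)) print(tidy(x), ...)
  invisible(x)
}

#' Tidy a cross-validated SCAD fit
#'
#' @param x A [cv_ahaz_scad()] object.
#' @param ... Unused.
#' @return A tibble of nonzero-path terms: `term`, `role`, `estimate`.
#' @method tidy cv_ahaz_scad
#' @export
tidy.cv_ahaz_scad <- function(x, ...) {
  tibble(term = names(x$coefficients), role = x$roles,
         estimate = unname(x$coefficients))
}

#' @rdname tidy.cv_ahaz_scad
#' @method glance cv_ahaz_scad
#' @export
glance.cv_ahaz_scad <- function(x, ...) {
  tibble(lambda_star = x$lambda_star, n_selected = nrow(x$selected),
         n_lambda = nrow(x$cv_curve), n_folds = x$n_folds,
         penalty = x$penalty, converged = x$converged)
}
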