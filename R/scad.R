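#' SCAD penalty derivative
#'
#' The derivative of the smoothly clipped absolute deviation penalty,
#' \deqn{p'_\lambda(|\beta|) = \lambda I(|\beta| \le \lambda) +
#'   \frac{(a\lambda - |\beta|)_+}{a - 1} I(|\beta| > \lambda),}
#' constant at \eqn{\lambda} near zero, linearly decaying to 0 at
#' \eqn{a\lambda}: sparse like the lasso near the origin, nearly unbiased
#' for large coefficients.
#'
#' @param beta_abs Nonnegative coefficient magnitude(s).
#' @param lambda Penalty level (> 0).
#' @param a Concavity parameter (> 2); 3.7 is the conventional default.
#' @return Vector of derivative values.
#' @examples
#' scad_deriv(c(0.5, 2, 4), lambda = 1)
#' @export
scad_deriv <- function(beta_abs, lambda, a = 3.7) {
  check_scad_params(lambda, a)
  if (any(beta_abs < 0)) stop_bad_arg("`beta_abs` must be nonnegative.")
  ifelse(beta_abs <= lambda, lambda, pmax(a * lambda - beta_abs, 0) / (a - 1))
}

#' SCAD penalty function
#'
#' The antiderivative of [scad_deriv()] with \eqn{p_\lambda(0) = 0};
#' quadratic on the middle branch and constant
#' \eqn{\lambda^2 (a + 1) / 2} beyond \eqn{a\lambda}.
#' @inheritParams scad_deriv
#' @return Vector of penalty values.
#' @export
scad_penalty <- function(beta_abs, lambda, a = 3.7) {
  check_scad_params(lambda, a)
  if (any(beta_abs < 0)) stop_bad_arg("`beta_abs` must be nonnegative.")
  ifelse(beta_abs <= lambda,
         lambda * beta_abs,
         ifelse(beta_abs <= a * lambda,
                (2 * a * lambda * beta_abs - beta_abs^2 - lambda^2) / (2 * (a - 1)),
                lambda^2 * (a + 1) / 2))
}

check_scad_params <- function(lambda, a) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop_bad_arg("`lambda` must be positive.")
  if (!is.finite(a) || a <= 2) stop_bad_arg("`a` must exceed 2 for the SCAD penalty.")
  invisible(NULL)
}

#' Penalized Lin-Ying fit by cyclic coordinate descent
#'
#' Minimizes the penalized least-squares-type objective
#' \deqn{Q(\beta) = \tfrac12 \beta^T V \beta - b^T \beta +
#'       \sum_{j \in \mathrm{penalized}} p_\lambda(|\beta_j|)}
#' by cyclic coordinate descent: each coordinate update solves the exact
#' univariate SCAD-penalized quadratic in closed form against the partial
#' residual, so the objective never increases across sweeps.  A descending
#' `lambda` vector is solved as a warm-started path.
#'
#' @param stats An [ahaz_statistics()] object (b, V on the chosen design).
#' @param penalized Logical mask per design column; exposure and covariate
#'   columns are conventionally unpenalized.
#' @param lambda Positive penalty level(s), descending if more than one.
#' @param a SCAD concavity parameter (> 2).
#' @param penalty `"scad"` or `"lasso"` (soft-threshold special case).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Sweep budget per lambda.
#' @param warm_start Optional initial coefficient vector.
#' @param check_objective Assert objective monotonicity every sweep (debug).
#' @return A list: `beta` (m x n_lambda matrix, design column names on
#'   rows), `lambda`, `iters`, `converged`.
#' @export
ahaz_penalized_fit <- function(stats, penalized, lambda, a = 3.7,
                               penalty = c("scad", "lasso"), tol = 1e-7,
                               max_iter = 10000L, warm_start = NULL,
                               check_objective = FALSE) {
  penalty <- match.arg(penalty)
  if (penalty == "scad") check_scad_params(lambda, a)
  if (any(lambda <= 0)) stop_bad_arg("`lambda` must be positive.")
  if (length(lambda) > 1 && any(diff(lambda) >= 0)) {
    stop_bad_arg("`lambda` must be strictly descending along a path.")
  }
  m <- length(stats$b)
  if (length(penalized) != m) stop_bad_arg("`penalized` mask length must match the design.")
  beta0 <- warm_start %||% rep(0, m)
  res <- scad_cd_path(stats$V, stats$b, as.logical(penalized),
                      as.double(lambda), a, tol, as.integer(max_iter),
                      penalty == "lasso", as.double(beta0), check_objective)
  if (isTRUE(res$objective_increased)) {
    abort("penalized objective increased across a coordinate-descent sweep")
  }
  if (!all(res$converged)) {
    warn(sprintf("coordinate descent did not converge for %d lambda value(s) within %d sweeps",
                 sum(!res$converged), max_iter))
  }
  rownames(res$beta) <- stats$terms
  list(beta = res$beta, lambda = lambda, iters = res$iters,
       converged = res$converged)
}

# Smallest lambda that zeroes every penalized coefficient: solve the
# unpenalized block alone, then take the largest absolute partial residual
# over penalized columns (the soft-threshold activation bound).
lambda_max_bound <- function(stats, penalized) {
  un <- which(!penalized)
  beta <- rep(0, length(stats$b))
  if (length(un)) {
    beta[un] <- solve_guarded(stats$V[un, un, drop = FALSE], stats$b[un],
                              stats$terms[un])
  }
  z <- stats$b - drop(stats$V %*% beta)
  max(abs(z[penalized]))
}

default_lambda_grid <- function(stats, penalized, nlambda = 50,
                                lambda_min_ratio = 0.001) {
  lmax <- lambda_max_bound(stats, penalized)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Cross-validated SCAD selection of mediators on the screened subset
#'
#' The penalized-selection step: on the design (exposure, covariates,
#' screened mediators S1) it minimizes the penalized Lin-Ying objective over
#' a descending lambda path, chooses lambda by k-fold cross-validation of
#' the held-out quadratic loss \eqn{\tfrac12 \hat\beta^T V_{test} \hat\beta -
#' b_{test}^T \hat\beta} (folds stratified by event status), refits on all
#' subjects at the chosen lambda, and reports the selected subset
#' \eqn{S_2 = \{k: \hat\beta_k \ne 0\}}.  Exposure and covariates are never
#' penalized unless `penalize_all = TRUE`.
#'
#' @inheritParams sis_screen
#' @param s1 A [sis_screen()] result, or an integer vector of mediator
#'   indices to use as the screened subset.
#' @param lambda Optional descending grid; by default 50 log-spaced values
#'   from the activation bound `lambda_max` down to `0.001 * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and lower ratio when `lambda`
#'   is `NULL`.
#' @param a SCAD concavity parameter.
#' @param penalty `"scad"` (default) or `"lasso"`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param design `"mediators"` (default) penalizes the screened mediator
#'   columns alone, so each mediator competes on its full marginal hazard
#'   signal — including the part transmitted from the exposure, which is
#'   what makes a mediator worth keeping.  `"adjusted"` additionally keeps
#'   exposure and covariates in the penalized model as unpenalized columns,
#'   which conditions the mediator signals on the exposure (a much weaker,
#'   purely outcome-side criterion); available for sensitivity analysis.
#' @param penalize_all With `design = "adjusted"`, also penalize exposure
#'   and covariates (sensitivity flag; default `FALSE`).
#' @param tol,max_iter Coordinate-descent controls.
#' @param seed Integer seed for the fold partition.
#' @return An object of class `cv_ahaz_scad`: `coefficients` (named, full
#'   S1 design), `selected` (tibble: mediator, index, coefficient),
#'   `lambda_star`, `cv_curve` (tibble: lambda, cv_loss, n_selected),
#'   `converged`, plus the design bookkeeping.
#' @examples
#' sim <- simulate_survmed(sim_scenario(n = 200, p = 50, censor_upper = 2))
#' cv <- cv_ahaz_scad(sim, sis_screen(sim), seed = 7)
#' cv$selected
#' @export
cv_ahaz_scad <- function(data, s1 = NULL, lambda = NULL, nlambda = 50,
                         lambda_min_ratio = 0.001, a = 3.7,
                         penalty = c("scad", "lasso"), n_folds = 5,
                         design = c("mediators", "adjusted"),
                         penalize_all = FALSE, tol = 1e-7, max_iter = 10000L,
                         seed = 1L, ...) {
  data <- as_survmed_data(data, ...)
  penalty <- match.arg(penalty)
  design <- match.arg(design)
  n <- length(data$time)
  if (n < 2 * n_folds) stop_bad_arg("Need at least two subjects per fold.")
  idx <- if (is.null(s1)) seq_len(ncol(data$mediators))
         else if (inherits(s1, "sis_screen")) screened_indices(s1)
         else as.integer(s1)
  des <- if (design == "mediators") {
    Q <- data$mediators[, idx, drop = FALSE]
    colnames(Q) <- data$mediator_names[idx]
    list(Q = Q, roles = rep("mediator", length(idx)), mediators_idx = idx)
  } else {
    build_design(data, idx)
  }
  stats <- ahaz_statistics(data$time, data$status, des$Q)
  penalized <- if (penalize_all) rep(TRUE, ncol(des$Q)) else des$roles == "mediator"
  if (!any(penalized)) stop_bad_arg("Nothing to penalize: empty screened subset.")
  if (is.null(lambda)) {
    lambda <- default_lambda_grid(stats, penalized, nlambda, lambda_min_ratio)
  }
  lambda <- sort(unique(as.double(lambda)), decreasing = TRUE)

  # Verweij-van Houwelingen held-out loss: the test contribution of fold f is
  # the full-sample loss minus the training loss (subject-sum scale), so the
  # risk-set averages of the held-out part are evaluated inside the full
  # sample rather than from the small fold alone.
  folds <- draw_folds(data$status, n_folds, seed)
  quad_loss <- function(stats_, beta_mat) {
    0.5 * colSums(beta_mat * (stats_$V %*% beta_mat)) -
      drop(crossprod(stats_$b, beta_mat))
  }
  cv_loss <- numeric(length(lambda))
  for (f in seq_len(n_folds)) {
    train <- folds != f
    stats_tr <- ahaz_statistics(data$time[train], data$status[train],
                                des$Q[train, , drop = FALSE])
    path <- ahaz_penalized_fit(stats_tr, penalized, lambda, a = a,
                               penalty = penalty, tol = tol, max_iter = max_iter)
    cv_loss <- cv_loss + n * quad_loss(stats, path$beta) -
      sum(train) * quad_loss(stats_tr, path$beta)
  }

  full_path <- ahaz_penalized_fit(stats, penalized, lambda, a = a,
                                  penalty = penalty, tol = tol,
                                  max_iter = max_iter)
  n_sel <- colSums(full_path$beta[penalized & des$roles == "mediator", ,
                                  drop = FALSE] != 0)
  k_star <- which.min(cv_loss)           # ties resolve to the larger lambda
  coefs <- setNames(full_path$beta[, k_star], stats$terms)
  med_cols <- which(des$roles == "mediator")
  sel <- med_cols[coefs[med_cols] != 0]
  idx_orig <- des$mediators_idx[match(sel, med_cols)]
  selected <- tibble(mediator = data$mediator_names[idx_orig],
                     index = idx_orig,
                     coefficient = unname(coefs[sel]))

  structure(
    list(coefficients = coefs, selected = selected,
         lambda_star = lambda[k_star],
         cv_curve = tibble(lambda = lambda, cv_loss = cv_loss,
                           n_selected = as.integer(n_sel)),
         converged = all(full_path$converged),
         screened_indices = des$mediators_idx, roles = des$roles,
         penalty = penalty, a = a, n_folds = n_folds, design = design,
         seed = seed),
    class = "cv_ahaz_scad"
  )
}

# Seeded fold partition stratified by event status; redraws (up to 10 times)
# until every held-out fold contains at least one event.
draw_folds <- function(status, n_folds, seed) {
  n <- length(status)
  rng <- local({
    set.seed(seed)
    function(k) sample.int(k)
  })
  for (attempt in 1:10) {
    folds <- integer(n)
    for (s in unique(status)) {
      who <- which(status == s)
      folds[who] <- rep_len(seq_len(n_folds), length(who))[rng(length(who))[seq_along(who)]]
    }
    ev_per_fold <- vapply(seq_len(n_folds), function(f) sum(status[folds == f]), 0)
    if (all(ev_per_fold >= 1)) return(folds)
  }
  abort("could not build folds with at least one event each after 10 attempts",
        class = "ahazmed_bad_folds")
}

#' @export
print.cv_ahaz_scad <- function(x, ...) {
  cat(sprintf("<cv_ahaz_scad> %s penalty, %d-fold CV over %d lambdas\n",
              x$penalty, x$n_folds, nrow(x$cv_curve)))
  cat(sprintf("  lambda* = %.4g, |S2| = %d mediator(s)\n",
              x$lambda_star, nrow(x$selected)))
  if (nrow(x$selected)) print(x$selected, ...)
  invisible(x)
}
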