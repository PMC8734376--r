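#' @section Counting-process statistics:
#' With \eqn{N_i(t) = I(T_i \le t, \delta_i = 1)} and at-risk indicator
#' \eqn{Y_i(t) = I(T_i \ge t)}, the Lin-Ying pseudo-score of the additive
#' hazards model \eqn{\lambda_i(t) = \lambda_0(t) + P^T Q_i} is
#' \eqn{U(P) = b - VP} with
#' \deqn{b = n^{-1} \sum_i \int (Q_i - \bar Q(t))\, dN_i(t), \qquad
#'       V = n^{-1} \sum_i \int Y_i(t) (Q_i - \bar Q(t))^{\otimes 2} dt,}
#' where \eqn{\bar Q(t)} is the at-risk average of the regressor rows.  Both
#' integrals are piecewise constant between observed times and are evaluated
#' exactly as finite sums over the ordered distinct times.
#' @name hazard-statistics
#' @keywords internal
NULL

# Shared risk-set layout for a set of observed times.  Interval j is
# (t_{j-1}, t_j] with t_0 = 0; on its interior the risk set is {i: T_i >= t_j}
# because observed times take no values inside the interval.
risk_structure <- function(time) {
  ord <- order(time)
  ts <- time[ord]
  uniq <- !duplicated(ts, fromLast = TRUE)      # last index of each distinct time
  tj <- ts[uniq]                                 # distinct times ascending
  first_idx <- which(!duplicated(ts))            # first subject at each distinct time
  delta_t <- diff(c(0, tj))
  nrisk <- length(ts) - first_idx + 1L
  list(ord = ord, tj = tj, first_idx = first_idx, delta_t = delta_t,
       nrisk = nrisk, interval_of = match(time, tj))
}

# Suffix (at-risk) column sums of a sorted matrix, evaluated at the first
# subject of each distinct time: row j = sum over {i: T_i >= t_j} of Q_i.
# Group rows by distinct time (C-level rowsum), then accumulate from the
# largest time backwards; much cheaper than per-column cumulative sums when
# the matrix is wide.
suffix_sums <- function(Q_sorted, first_idx) {
  n <- nrow(Q_sorted)
  K <- length(first_idx)
  g <- rep.int(seq_len(K), diff(c(first_idx, n + 1L)))
  G <- rowsum(Q_sorted, g, reorder = FALSE)
  if (K > 1L) {
    for (j in (K - 1L):1L) G[j, ] <- G[j, ] + G[j + 1L, ]
  }
  G
}

#' Lin-Ying score statistics b, V and D for a regressor matrix
#'
#' Computes the intercept-free least-squares-type statistics of the additive
#' hazards model: the score offset `b`, the curvature matrix `V` and the
#' outer-product matrix `D` of centered score increments at event times,
#' used for the sandwich covariance.  All integrals are exact finite sums
#' over the distinct observed times (see \link{hazard-statistics}).
#'
#' @param time,status Observed times (> 0) and event indicators (0/1).
#' @param Q Numeric matrix of per-subject regressor rows (n x m).
#' @return A list of class `ahaz_statistics`: `b` (length m), `V`, `D`
#'   (m x m symmetric PSD), `n`, `n_events`, `terms` (column names).
#' @examples
#' s <- ahaz_statistics(c(1, 2), c(1, 1), cbind(x = c(0, 1)))
#' s$b  # -0.25
#' @export
ahaz_statistics <- function(time, status, Q) {
  Q <- as.matrix(Q)
  storage.mode(Q) <- "double"
  n <- length(time)
  if (n < 2L) stop_bad_arg("At least two subjects are required.")
  if (length(status) != n || nrow(Q) != n) {
    stop_bad_arg("`time`, `status` and `Q` must agree on the number of subjects.")
  }
  if (anyNA(time) || anyNA(status) || anyNA(Q) || any(!is.finite(Q))) {
    stop_bad_arg("NaN/NA/Inf values in the inputs.")
  }
  if (any(time <= 0)) stop_bad_arg("All times must be positive.")
  if (!all(status %in% c(0, 1))) stop_bad_arg("`status` must be 0/1.")
  if (sum(status) < 1) {
    abort("no observed failures", class = "ahazmed_no_events")
  }

  rs <- risk_structure(time)
  Qs <- Q[rs$ord, , drop = FALSE]
  S1 <- suffix_sums(Qs, rs$first_idx)              # K x m at-risk sums
  Qbar <- S1 / rs$nrisk

  # V = (1/n) [ sum_i T_i Q_i Q_i^T  -  sum_j dt_j * nrisk_j * Qbar_j Qbar_j^T ]
  # (first term telescopes the interval lengths each subject is at risk).
  A <- Qbar * sqrt(rs$delta_t * rs$nrisk)
  V <- (crossprod(Q, Q * time) - crossprod(A)) / n
  V <- (V + t(V)) / 2

  ev <- status == 1
  centered <- Q[ev, , drop = FALSE] - Qbar[rs$interval_of[ev], , drop = FALSE]
  b <- colSums(centered) / n
  D <- crossprod(centered) / n

  terms <- colnames(Q) %||% paste0("q", seq_len(ncol(Q)))
  structure(list(b = unname(b), V = unname(V), D = unname(D), n = n,
                 n_events = sum(ev), terms = terms),
            class = "ahaz_statistics")
}

# Symmetric solve with a condition-number guard; names offending columns on
# failure rather than silently regularizing (a rank-deficient V would corrupt
# every downstream Sobel standard error).
solve_guarded <- function(V, b, terms, cond_tol = 1e12) {
  rc <- tryCatch(rcond(V), error = function(e) 0)
  if (!is.finite(rc) || rc < 1 / cond_tol) {
    qrV <- qr(V)
    bad <- if (qrV$rank < ncol(V)) {
      terms[qrV$pivot[seq.int(qrV$rank + 1L, ncol(V))]]
    } else {
      d <- abs(diag(qr.R(qrV)))
      terms[d <= max(d) * ncol(V) * .Machine$double.eps * 1e4]
    }
    abort(sprintf(
      "V is singular or ill-conditioned (rcond %.2e); offending column(s): %s",
      rc, paste(bad, collapse = ", ")
    ), class = "ahazmed_singular")
  }
  drop(solve(V, b))
}

new_ahaz_fit <- function(stats, estimates, covariance, roles) {
  grad <- max(abs(stats$V %*% estimates - stats$b))
  if (grad > 1e-8 * (1 + max(abs(stats$b)))) {
    abort(sprintf("internal solver failure: score gradient %.3e not ~0", grad))
  }
  se <- sqrt(pmax(diag(covariance), 0))
  structure(
    list(estimates = setNames(estimates, stats$terms),
         std_errors = setNames(se, stats$terms),
         covariance = covariance, statistics = stats, roles = roles),
    class = "ahaz_fit"
  )
}

#' Fit the additive hazards model by the Lin-Ying estimating equation
#'
#' Solves \eqn{V \hat P = b} for the regression design
#' \eqn{Q_i = (X_i, Z_i, M_{S,i})} (exposure, covariates, and an optional
#' subset of mediators) and returns sandwich standard errors
#' \eqn{\widehat{\mathrm{cov}}(\hat P) = V^{-1} D V^{-1} / n}.  Under the
#' additive hazards model coefficients are hazard-rate differences per unit
#' of the regressor.
#'
#' @inheritParams sis_screen
#' @param mediators_idx Integer indices of mediator columns to include in
#'   the design (default none: exposure + covariates only, the
#'   "total-effect" fit).
#' @param ... Column mapping passed to [survmed_data()] when `data` is a
#'   plain data frame.
#' @return An `ahaz_fit` object; see [tidy.ahaz_fit()] for a tibble of
#'   coefficients.
#' @examples
#' sim <- simulate_survmed(sim_scenario(n = 150, p = 5, censor_upper = 2))
#' fit <- ahaz_fit(sim, mediators_idx = 1:2)
#' tidy(fit)
#' @export
ahaz_fit <- function(data, mediators_idx = integer(), ...) {
  data <- as_survmed_data(data, ...)
  des <- build_design(data, mediators_idx)
  stats <- ahaz_statistics(data$time, data$status, des$Q)
  fit_from_statistics(stats, des$roles)
}

fit_from_statistics <- function(stats, roles) {
  estimates <- solve_guarded(stats$V, stats$b, stats$terms)
  Vi <- solve(stats$V)
  covariance <- Vi %*% stats$D %*% Vi / stats$n
  new_ahaz_fit(stats, estimates, covariance, roles)
}

# Design bundle: regressor matrix plus a role tag per column, in the fixed
# order exposure | covariates | mediators.
build_design <- function(data, mediators_idx = integer()) {
  p <- ncol(data$mediators)
  mediators_idx <- as.integer(mediators_idx)
  if (length(mediators_idx) &&
      (min(mediators_idx) < 1L || max(mediators_idx) > p)) {
    stop_bad_arg(sprintf("Mediator index out of range 1..%d.", p))
  }
  q <- ncol(data$covariates)
  Z <- data$covariates
  zn <- colnames(Z) %||% (if (q) paste0("Z", seq_len(q)) else character())
  Q <- cbind(data$exposure, Z, data$mediators[, mediators_idx, drop = FALSE])
  colnames(Q) <- c("exposure", zn, data$mediator_names[mediators_idx])
  roles <- c("exposure", rep("covariate", q), rep("mediator", length(mediators_idx)))
  list(Q = Q, roles = roles, mediators_idx = mediators_idx)
}

#' Marginal additive-hazards fit for a single mediator
#'
#' Fits the design (exposure, covariates, one mediator); the building block
#' of the naive per-mediator baseline and of the outcome-side screening
#' statistic.
#'
#' @inheritParams ahaz_fit
#' @param k Mediator index (1-based).
#' @return An `ahaz_fit` on the three-block design.
#' @export
marginal_ahaz_fit <- function(data, k, ...) {
  data <- as_survmed_data(data, ...)
  if (length(k) != 1L || k < 1L || k > ncol(data$mediators)) {
    stop_bad_arg(sprintf("`k` must be a single index in 1..%d.", ncol(data$mediators)))
  }
  ahaz_fit(data, mediators_idx = k)
}

#' Marginal additive-hazards coefficients for every mediator at once
#'
#' Vectorized equivalent of calling [marginal_ahaz_fit()] for each of the p
#' mediators: the (exposure, covariate) block of b, V and D is computed once
#' and each mediator contributes only its cross terms, solved by a Schur
#' complement.  Returns the mediator coefficient and its sandwich standard
#' error per column.
#'
#' @inheritParams ahaz_fit
#' @return A tibble with columns `mediator`, `index`, `beta_hat`, `beta_se`.
#' @export
marginal_ahaz_all <- function(data, ...) {
  data <- as_survmed_data(data, ...)
  time <- data$time; status <- data$status
  n <- length(time)
  A <- build_design(data)$Q                     # exposure + covariates
  M <- data$mediators
  p <- ncol(M)

  rs <- risk_structure(time)
  As <- A[rs$ord, , drop = FALSE]
  Ms <- M[rs$ord, , drop = FALSE]
  S1A <- suffix_sums(As, rs$first_idx)
  S1M <- suffix_sums(Ms, rs$first_idx)
  Abar <- S1A / rs$nrisk
  Mbar <- S1M / rs$nrisk
  w <- rs$delta_t * rs$nrisk

  statsA <- ahaz_statistics(time, status, A)
  VA <- statsA$V; bA <- statsA$b; DA <- statsA$D

  # cross and diagonal blocks of V for each mediator
  Vcross <- (crossprod(A, M * time) - crossprod(Abar * w, Mbar)) / n   # mA x p
  vMM <- (colSums(M * M * time) - colSums(Mbar * Mbar * w)) / n        # length p

  ev <- status == 1
  iv <- rs$interval_of[ev]
  cA <- A[ev, , drop = FALSE] - Abar[iv, , drop = FALSE]
  cM <- M[ev, , drop = FALSE] - Mbar[iv, , drop = FALSE]
  bM <- colSums(cM) / n
  Dcross <- crossprod(cA, cM) / n
  dMM <- colSums(cM * cM) / n

  VAi <- solve(VA)
  W <- VAi %*% Vcross                                     # mA x p
  schur <- vMM - colSums(Vcross * W)
  ok <- schur > max(vMM, 1) * 1e-12
  beta <- rep(NA_real_, p)
  beta[ok] <- (bM[ok] - drop(crossprod(W, bA))[ok]) / schur[ok]

  # variance of the mediator coefficient: last row of V^{-1} is r = (-u, 1)/s
  uDu <- colSums(W * (DA %*% W))
  uDx <- colSums(W * Dcross)
  varb <- rep(NA_real_, p)
  varb[ok] <- pmax((uDu - 2 * uDx + dMM)[ok] / schur[ok]^2 / n, 0)

  tibble(mediator = data$mediator_names, index = seq_len(p),
         beta_hat = beta, beta_se = sqrt(varb))
}

#' @export
print.ahaz_fit <- function(x, ...) {
  cat(sprintf("<ahaz_fit> additive hazards model, n = %d (%d events)\n",
              x$statistics$n, x$statistics$n_events))
  print(tidy(x), ...)
  invisible(x)
}
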