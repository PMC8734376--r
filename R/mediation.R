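#' Exposure-to-mediator regression for one mediator
#'
#' Ordinary least squares of mediator k on (intercept, exposure,
#' covariates): \eqn{M_k = c_k + \alpha_k X + \vartheta^T Z + e_k}.  The
#' classical OLS standard error of \eqn{\hat\alpha_k} feeds the Sobel test.
#'
#' @inheritParams ahaz_fit
#' @param k Mediator index.
#' @return A list of class `alpha_fit`: `alpha_hat`, `alpha_se`,
#'   `intercept`, `covariate_effects`, `sigma`, `degenerate` (TRUE when the
#'   residuals vanish and the standard error is 0).
#' @export
fit_alpha <- function(data, k, ...) {
  data <- as_survmed_data(data, ...)
  p <- ncol(data$mediators)
  if (length(k) != 1L || k < 1L || k > p) {
    stop_bad_arg(sprintf("`k` must be a single index in 1..%d.", p))
  }
  af <- fit_alpha_all(data, k)
  structure(
    list(alpha_hat = af$alpha_hat, alpha_se = af$alpha_se,
         intercept = af$intercept, covariate_effects = af$covariate_effects[[1]],
         sigma = af$sigma, degenerate = af$alpha_se == 0),
    class = "alpha_fit"
  )
}

# Vectorized OLS of each requested mediator column on (1, X, Z): one
# normal-equation solve shared across columns.  `details = FALSE` skips the
# per-mediator covariate-coefficient lists (costly at p ~ 10^4).
fit_alpha_all <- function(data, idx = seq_len(ncol(data$mediators)),
                          details = TRUE) {
  n <- length(data$time)
  X4 <- cbind(1, data$exposure, data$covariates)
  if (sd(data$exposure) == 0) {
    stop_bad_arg("Exposure is constant; the mediator model is not identified.")
  }
  XtX <- crossprod(X4)
  if (rcond(XtX) < 1e-12) {
    abort("exposure and covariates are collinear in the mediator model",
          class = "ahazmed_singular")
  }
  XtXi <- solve(XtX)
  M <- data$mediators[, idx, drop = FALSE]
  coefs <- XtXi %*% crossprod(X4, M)               # (2+q) x |idx|
  R <- M - X4 %*% coefs
  dfree <- n - nrow(coefs)
  sigma2 <- colSums(R^2) / dfree
  # an exactly exposure-determined mediator leaves only rounding noise in the
  # residuals; report its standard error as the exact zero it represents
  sigma2[sigma2 < 1e-24 * pmax(colSums(M^2), 1)] <- 0
  out <- tibble(
    index = idx, mediator = data$mediator_names[idx],
    alpha_hat = unname(coefs[2, ]),
    alpha_se = unname(sqrt(pmax(sigma2 * XtXi[2, 2], 0))),
    intercept = unname(coefs[1, ]),
    sigma = unname(sqrt(pmax(sigma2, 0)))
  )
  if (details) {
    out$covariate_effects <- lapply(seq_along(idx), function(j) coefs[-(1:2), j])
  }
  out
}

#' Sobel test of an indirect effect
#'
#' Tests \eqn{H_0: \alpha_k \beta_k = 0} by the normal approximation to the
#' product of coefficients, with
#' \deqn{\hat\sigma_{\alpha\beta} = \sqrt{\hat\alpha^2 \hat\sigma_\beta^2 +
#'  \hat\beta^2 \hat\sigma_\alpha^2}, \qquad
#'  p = 2\{1 - \Phi(|\hat\alpha\hat\beta| / \hat\sigma_{\alpha\beta})\}.}
#' All arguments are vectorized.
#'
#' @param alpha_hat,alpha_se Exposure-to-mediator estimate and its SE.
#' @param beta_hat,beta_se Mediator-to-hazard estimate and its SE.
#' @return A tibble: `ie_hat`, `sobel_se`, `statistic`, `p_raw`.
#' @examples
#' sobel_test(1, 0.5, 1, 0.5)  # z = sqrt(2), p ~ 0.157
#' @export
sobel_test <- function(alpha_hat, alpha_se, beta_hat, beta_se) {
  if (any(alpha_se < 0) || any(beta_se < 0)) {
    stop_bad_arg("Standard errors must be nonnegative.")
  }
  ie <- alpha_hat * beta_hat
  se <- sqrt(alpha_hat^2 * beta_se^2 + beta_hat^2 * alpha_se^2)
  if (any(se == 0 & ie != 0)) {
    abort("degenerate Sobel variance: zero standard error with nonzero indirect effect",
          class = "ahazmed_degenerate")
  }
  z <- ifelse(se > 0, abs(ie) / se, 0)
  tibble(ie_hat = ie, sobel_se = se, statistic = z,
         p_raw = 2 * (1 - pnorm(z)))
}

#' False-discovery-rate adjustment of Sobel p values
#'
#' Benjamini-Hochberg step-up values, or Benjamini-Yekutieli (BH scaled by
#' the harmonic sum \eqn{\sum_{i=1}^m 1/i}) for arbitrarily dependent
#' hypotheses.  Thin, validated wrapper over [stats::p.adjust()].
#'
#' @param p Vector of raw p values in \[0, 1\].
#' @param method `"bh"` or `"by"`.
#' @return Adjusted p values (monotone, capped at 1).
#' @export
adjust_pvalues <- function(p, method = c("bh", "by")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_bad_arg("p values must lie in [0, 1].")
  p.adjust(p, method = toupper(method))
}

#' Joint-significance combination of the two pathway p values
#'
#' The joint significance (max-p) test declares mediation only when both the
#' exposure-to-mediator and mediator-to-outcome coefficients are individually
#' significant: its p value is the larger of the two.
#'
#' @param alpha_p,beta_p P values for the two path coefficients.
#' @return `pmax(alpha_p, beta_p)`.
#' @export
joint_significance_test <- function(alpha_p, beta_p) {
  if (any(c(alpha_p, beta_p) < 0 | c(alpha_p, beta_p) > 1)) {
    stop_bad_arg("p values must lie in [0, 1].")
  }
  pmax(alpha_p, beta_p)
}

#' Joint refit and indirect-effect testing on a selected mediator subset
#'
#' One unpenalized additive-hazards refit on (exposure, covariates,
#' \eqn{M_{S_2}}) supplies every \eqn{\hat\beta_k} with its sandwich SE
#' (penalized coefficients carry no tractable SE and are biased, so the
#' refit is the post-selection estimate); OLS per mediator supplies
#' \eqn{\hat\alpha_k}.  Sobel p values are adjusted across the \eqn{|S_2|}
#' hypotheses by both BH and BY; `significant` flags the chosen adjustment
#' at `level`.
#'
#' @inheritParams ahaz_fit
#' @param s2 Integer vector of selected mediator indices.
#' @param adjust Which adjusted p value drives `significant`.
#' @param level Significance level on the adjusted p value.
#' @param test `"sobel"` (default) or `"joint"` (max-p combination of the
#'   two Wald path p values).
#' @param conf_level Wald confidence level for the indirect effect.
#' @return A tibble (one `mediation_record` row per mediator in `s2`):
#'   `mediator`, `index`, `alpha_hat`, `alpha_se`, `beta_hat`, `beta_se`,
#'   `ie_hat`, `sobel_se`, `p_raw`, `p_bh`, `p_by`, `ci_low`, `ci_high`,
#'   `significant`.  Attributes carry the joint refit (`refit`) and
#'   \eqn{\hat\gamma} (`gamma_hat`, `gamma_se`).
#' @export
refit_and_test <- function(data, s2, adjust = c("bh", "by"), level = 0.05,
                           test = c("sobel", "joint"), conf_level = 0.95, ...) {
  data <- as_survmed_data(data, ...)
  adjust <- match.arg(adjust)
  test <- match.arg(test)
  s2 <- sort(unique(as.integer(s2)))
  if (!length(s2)) {
    inform("empty selected subset: no indirect effects to test.")
    return(empty_records(attr_gamma = NA_real_))
  }
  n_events <- sum(data$status)
  if (length(s2) + 1 + ncol(data$covariates) >= n_events) {
    abort(sprintf(
      "selected subset too large (%d mediators, %d events): increase the penalty (larger lambda).",
      length(s2), n_events
    ), class = "ahazmed_overselected")
  }

  refit <- ahaz_fit(data, mediators_idx = s2)
  med_cols <- which(refit$roles == "mediator")
  beta_hat <- unname(refit$estimates[med_cols])
  beta_se <- unname(refit$std_errors[med_cols])
  alpha <- fit_alpha_all(data, s2)

  sob <- sobel_test(alpha$alpha_hat, alpha$alpha_se, beta_hat, beta_se)
  p_raw <- if (test == "sobel") {
    sob$p_raw
  } else {
    pa <- 2 * (1 - pnorm(abs(alpha$alpha_hat) / alpha$alpha_se))
    pb <- 2 * (1 - pnorm(abs(beta_hat) / beta_se))
    joint_significance_test(pa, pb)
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  rec <- tibble(
    mediator = data$mediator_names[s2], index = s2,
    alpha_hat = alpha$alpha_hat, alpha_se = alpha$alpha_se,
    beta_hat = beta_hat, beta_se = beta_se,
    ie_hat = sob$ie_hat, sobel_se = sob$sobel_se, p_raw = p_raw,
    p_bh = adjust_pvalues(p_raw, "bh"), p_by = adjust_pvalues(p_raw, "by"),
    ci_low = sob$ie_hat - zq * sob$sobel_se,
    ci_high = sob$ie_hat + zq * sob$sobel_se
  )
  rec$significant <- (if (adjust == "bh") rec$p_bh else rec$p_by) < level
  attr(rec, "refit") <- refit
  attr(rec, "gamma_hat") <- unname(refit$estimates["exposure"])
  attr(rec, "gamma_se") <- unname(refit$std_errors["exposure"])
  attr(rec, "adjust") <- adjust
  rec
}

empty_records <- function(attr_gamma = NA_real_) {
  rec <- tibble(
    mediator = character(), index = integer(), alpha_hat = numeric(),
    alpha_se = numeric(), beta_hat = numeric(), beta_se = numeric(),
    ie_hat = numeric(), sobel_se = numeric(), p_raw = numeric(),
    p_bh = numeric(), p_by = numeric(), ci_low = numeric(),
    ci_high = numeric(), significant = logical()
  )
  attr(rec, "gamma_hat") <- attr_gamma
  rec
}

#' Total, direct and indirect effect decomposition
#'
#' Under the additive hazards mediation model the counterfactual hazard
#' difference for an exposure change \eqn{x \to x^*} decomposes exactly:
#' \deqn{TE = \gamma (x^* - x) + \Big(\sum_k \alpha_k \beta_k\Big)(x^* - x)
#'       = DE + IE.}
#' `te_marginal` additionally reports the exposure coefficient from the
#' mediator-free fit times the contrast — the finite-sample "total effect"
#' a marginal model would report; the two differ in finite samples and both
#' are useful diagnostics.
#'
#' @param gamma_hat Exposure coefficient from the joint refit (with
#'   mediators); its SE via `gamma_se` for a Wald CI.
#' @param records Mediation records from [refit_and_test()].
#' @param x,x_star Reference and comparison exposure values (defaults 0, 1,
#'   the binary-exposure contrast).
#' @param gamma_se,marginal_gamma,marginal_gamma_se Optional standard
#'   errors / mediator-free exposure coefficient for the reported intervals.
#' @return A one-row tibble of class `effect_decomposition`: `te`, `de`,
#'   `ie_total`, `exposure_contrast`, `de_ci_low`, `de_ci_high`,
#'   `te_marginal`, `te_marginal_ci_low`, `te_marginal_ci_high`.
#' @export
decompose_effects <- function(gamma_hat, records, x = 0, x_star = 1,
                              gamma_se = NA_real_, marginal_gamma = NA_real_,
                              marginal_gamma_se = NA_real_) {
  dx <- x_star - x
  if (dx == 0) warn("x and x* coincide; all effects are zero.")
  de <- gamma_hat * dx
  ie_total <- sum(records$ie_hat) * dx
  out <- tibble(
    te = de + ie_total, de = de, ie_total = ie_total, exposure_contrast = dx,
    de_ci_low = de - 1.96 * abs(dx) * gamma_se,
    de_ci_high = de + 1.96 * abs(dx) * gamma_se,
    te_marginal = marginal_gamma * dx,
    te_marginal_ci_low = marginal_gamma * dx - 1.96 * abs(dx) * marginal_gamma_se,
    te_marginal_ci_high = marginal_gamma * dx + 1.96 * abs(dx) * marginal_gamma_se
  )
  class(out) <- c("effect_decomposition", class(out))
  out
}

#' Full high-dimensional mediation procedure for survival data
#'
#' Chains the three steps on one dataset: (1) sure independence screening
#' of the p mediators down to \eqn{d = [2n/\log n]} (S1); (2)
#' cross-validated SCAD-penalized Lin-Ying selection on S1 (S2); (3) joint
#' unpenalized refit on S2, per-mediator Sobel tests with BH/BY adjustment,
#' and the TE = DE + IE decomposition.  Deterministic given
#' `(data, configuration, seed)`.
#'
#' @inheritParams sis_screen
#' @inheritParams cv_ahaz_scad
#' @inheritParams refit_and_test
#' @param screen_stat Screening utility, see [sis_screen()].
#' @param d Screened-subset size override.
#' @param x,x_star Exposure contrast for the decomposition.
#' @param tol,max_iter Coordinate-descent controls forwarded to
#'   [cv_ahaz_scad()].
#' @param quiet Suppress progress messages.
#' @return An object of class `mediate_ahaz` with elements `screen`
#'   ([sis_screen()] result), `scad` ([cv_ahaz_scad()] result), `records`
#'   (mediation tibble, see [refit_and_test()]), `decomposition`,
#'   `config`.  `tidy()` returns the records; `glance()` a one-row summary.
#' @examples
#' sim <- simulate_survmed(sim_scenario(n = 250, p = 100, censor_upper = 2))
#' res <- mediate_ahaz(sim, seed = 11)
#' glance(res)
#' @export
mediate_ahaz <- function(data, screen_stat = c("exposure_correlation", "marginal_hazard"),
                         d = NULL, lambda = NULL, nlambda = 50,
                         lambda_min_ratio = 0.001, a = 3.7,
                         penalty = c("scad", "lasso"), n_folds = 5,
                         design = c("mediators", "adjusted"),
                         adjust = c("bh", "by"), level = 0.05,
                         test = c("sobel", "joint"), x = 0, x_star = 1,
                         tol = 1e-7, max_iter = 10000L,
                         seed = 1L, quiet = TRUE, ...) {
  data <- as_survmed_data(data, ...)
  screen_stat <- match.arg(screen_stat)
  penalty <- match.arg(penalty)
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  test <- match.arg(test)
  say <- function(fmt, ...) if (!quiet) inform(sprintf(fmt, ...))

  say("step 1 (screening): p = %d mediators", ncol(data$mediators))
  screen <- with_stage("screening",
    sis_screen(data, statistic = screen_stat, d = d))
  say("  kept d = %d", attr(screen, "d"))

  say("step 2 (SCAD selection)")
  scad <- with_stage("scad",
    cv_ahaz_scad(data, s1 = screen, lambda = lambda, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, a = a, penalty = penalty,
                 n_folds = n_folds, design = design, tol = tol,
                 max_iter = max_iter, seed = seed))
  say("  |S2| = %d at lambda* = %.4g", nrow(scad$selected), scad$lambda_star)

  say("step 3 (Sobel tests and decomposition)")
  records <- with_stage("mediation",
    refit_and_test(data, scad$selected$index, adjust = adjust, level = level,
                   test = test))
  marg <- with_stage("mediation", ahaz_fit(data))
  gamma_hat <- attr(records, "gamma_hat")
  gamma_se <- attr(records, "gamma_se")
  if (is.null(gamma_hat) || is.na(gamma_hat)) {
    # empty selection: no joint refit, fall back to the mediator-free fit
    gamma_hat <- unname(marg$estimates["exposure"])
    gamma_se <- unname(marg$std_errors["exposure"])
  }
  decomposition <- decompose_effects(
    gamma_hat = gamma_hat,
    records = records, x = x, x_star = x_star,
    gamma_se = gamma_se %||% NA_real_,
    marginal_gamma = unname(marg$estimates["exposure"]),
    marginal_gamma_se = unname(marg$std_errors["exposure"])
  )

  structure(
    list(screen = screen, scad = scad, records = records,
         decomposition = decomposition,
         config = list(screen_stat = screen_stat, d = attr(screen, "d"),
                       penalty = penalty, a = a, n_folds = n_folds,
                       design = design, adjust = adjust, level = level,
                       test = test, x = x, x_star = x_star, seed = seed),
         n = length(data$time), p = ncol(data$mediators)),
    class = "mediate_ahaz"
  )
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", stage, conditionMessage(e)), parent = e)
    }),
    warning = function(w) {
      warn(sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
}

#' Naive per-mediator mediation baseline
#'
#' Estimates each mediator's indirect effect separately — marginal
#' additive-hazards fit (exposure, covariates, \eqn{M_k}) for
#' \eqn{\hat\beta_k}, OLS for \eqn{\hat\alpha_k}, Sobel test — and adjusts
#' across all p candidate mediators, with no variable selection.
#'
#' @inheritParams refit_and_test
#' @return A mediation-record tibble over all p mediators (same columns as
#'   [refit_and_test()]).
#' @export
naive_mediate_ahaz <- function(data, adjust = c("bh", "by"), level = 0.05, ...) {
  data <- as_survmed_data(data, ...)
  adjust <- match.arg(adjust)
  beta <- marginal_ahaz_all(data)
  alpha <- fit_alpha_all(data, details = FALSE)
  ok <- is.finite(beta$beta_hat) & is.finite(beta$beta_se)
  sob <- sobel_test(alpha$alpha_hat[ok], alpha$alpha_se[ok],
                    beta$beta_hat[ok], beta$beta_se[ok])
  p_raw <- rep(NA_real_, nrow(beta)); p_raw[ok] <- sob$p_raw
  rec <- tibble(
    mediator = beta$mediator, index = beta$index,
    alpha_hat = alpha$alpha_hat, alpha_se = alpha$alpha_se,
    beta_hat = beta$beta_hat, beta_se = beta$beta_se,
    ie_hat = alpha$alpha_hat * beta$beta_hat,
    sobel_se = NA_real_, p_raw = p_raw,
    p_bh = adjust_pvalues(p_raw, "bh"), p_by = adjust_pvalues(p_raw, "by")
  )
  rec$sobel_se[ok] <- sob$sobel_se
  rec$ci_low <- rec$ie_hat - 1.96 * rec$sobel_se
  rec$ci_high <- rec$ie_hat + 1.96 * rec$sobel_se
  padj <- if (adjust == "bh") rec$p_bh else rec$p_by
  rec$significant <- !is.na(padj) & padj < level
  attr(rec, "adjust") <- adjust
  rec
}
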