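#' Simulation scenario for the additive-hazards mediation design
#'
#' Describes one data-generating configuration: Bernoulli exposure
#' \eqn{X \sim B(1, 0.6)}, covariates \eqn{Z_1 \sim B(1, 0.3)},
#' \eqn{Z_2 \sim U(0, 1)}, mediators
#' \eqn{M_k = c_k + \alpha_k X + \vartheta^T Z + e_k} with
#' \eqn{c_k \sim U(0, 0.5)} and \eqn{e_k \sim N(0, 1)} (optionally
#' equicorrelated across mediators), and hazard
#' \eqn{\lambda(t) = 5t + \gamma X + \theta^T Z + \beta^T M} with uniform
#' censoring \eqn{C \sim U(0, c)} calibrated to a target rate.  The default
#' effect vectors put \eqn{\alpha = (1,1,1,1,0.5,0.5,0,\dots)} and
#' \eqn{\beta = (1,1,1,1,0,0,0.5,0.5,0,\dots)}, so the true mediators (both
#' paths nonzero) are the first four columns.
#'
#' @param n,p Subjects and mediators.
#' @param alpha_true,beta_true Length-p path coefficient vectors.
#' @param gamma_true Direct exposure effect on the hazard.
#' @param theta_true Covariate effects, recycled to both the hazard and the
#'   mediator model.
#' @param baseline_slope Slope of the baseline hazard \eqn{\lambda_0(t) =}
#'   `baseline_slope` \eqn{\cdot t}.
#' @param exposure_prob,intercept_range Exposure Bernoulli probability and
#'   the uniform range of the mediator intercepts \eqn{c_k}.
#' @param target_censoring Desired censoring proportion, used to calibrate
#'   `censor_upper` when the latter is `NULL`.
#' @param censor_upper Upper bound c of the censoring distribution; set it
#'   directly to skip calibration.
#' @param mediator_correlation Equicorrelation \eqn{\rho \ge 0} of the
#'   mediator errors (0 = independent).
#' @param seed Master seed for dataset generation.
#' @return A list of class `sim_scenario`; `truth` gives the indices with
#'   \eqn{\alpha_k \beta_k \ne 0}.
#' @export
sim_scenario <- function(n = 500, p = 10000,
                         alpha_true = default_alpha(p),
                         beta_true = default_beta(p),
                         gamma_true = 1, theta_true = c(0.4, 0.4),
                         baseline_slope = 5, exposure_prob = 0.6,
                         intercept_range = c(0, 0.5),
                         target_censoring = 0.15, censor_upper = NULL,
                         mediator_correlation = 0, seed = 1L) {
  if (length(alpha_true) != p || length(beta_true) != p) {
    stop_bad_arg("`alpha_true` and `beta_true` must have length p.")
  }
  if (mediator_correlation < 0 || mediator_correlation >= 1) {
    stop_bad_arg("`mediator_correlation` must lie in [0, 1).")
  }
  truth <- which(alpha_true * beta_true != 0)
  structure(
    list(n = n, p = p, alpha_true = alpha_true, beta_true = beta_true,
         gamma_true = gamma_true, theta_true = theta_true,
         baseline_slope = baseline_slope, exposure_prob = exposure_prob,
         intercept_range = intercept_range,
         target_censoring = target_censoring, censor_upper = censor_upper,
         mediator_correlation = mediator_correlation, seed = as.integer(seed),
         truth = truth),
    class = "sim_scenario"
  )
}

#' @rdname sim_scenario
#' @export
default_alpha <- function(p) {
  if (p < 8) stop_bad_arg("Default effect vectors need p >= 8.")
  c(1, 1, 1, 1, 0.5, 0.5, 0, 0, rep(0, p - 8))
}

#' @rdname sim_scenario
#' @export
default_beta <- function(p) {
  if (p < 8) stop_bad_arg("Default effect vectors need p >= 8.")
  c(1, 1, 1, 1, 0, 0, 0.5, 0.5, rep(0, p - 8))
}

# Linear predictor and event time for m subjects drawn under the scenario's
# distributions.  Event times invert the cumulative hazard
# Lambda(t) = (slope/2) t^2 + eta t at an Exp(1) draw through the positive
# quadratic root.
draw_event_times <- function(scn, m, eta = NULL) {
  if (is.null(eta)) eta <- draw_eta(scn, m)
  E <- rexp(m)
  s <- scn$baseline_slope
  D <- (-eta + sqrt(eta^2 + 2 * s * E)) / s
  list(D = D, E = E, eta = eta)
}

draw_eta <- function(scn, m) {
  X <- rbinom(m, 1, scn$exposure_prob)
  Z1 <- rbinom(m, 1, 0.3)
  Z2 <- runif(m)
  nz <- which(scn$beta_true != 0)
  ck <- runif(length(nz), scn$intercept_range[1], scn$intercept_range[2])
  lp_z <- scn$theta_true[1] * Z1 + scn$theta_true[2] * Z2
  eta <- scn$gamma_true * X + lp_z
  if (length(nz)) {
    Ek <- matrix(rnorm(m * length(nz)), m, length(nz))
    Mk <- matrix(ck, m, length(nz), byrow = TRUE) +
      outer(X, scn$alpha_true[nz]) + lp_z + Ek
    eta <- eta + drop(Mk %*% scn$beta_true[nz])
  }
  eta
}

#' Calibrate the censoring upper bound to a target rate
#'
#' Finds the constant c of the censoring distribution \eqn{C \sim U(0, c)}
#' giving the requested censoring proportion under the scenario.  A fixed
#' Monte-Carlo batch of event times (default 20,000 subjects, fixed
#' calibration seed) makes the realized rate \eqn{E[\min(D/c, 1)]} a smooth
#' monotone function of c, solved by root finding to within 0.5%.
#'
#' @param scenario A [sim_scenario()].
#' @param target Censoring proportion in (0.05, 0.95); defaults to the
#'   scenario's `target_censoring`.
#' @param n_mc Monte-Carlo subjects per evaluation.
#' @param calibration_seed Seed of the Monte-Carlo batch (fixed so that the
#'   calibration is reproducible and independent of dataset seeds).
#' @return The calibrated upper bound c.
#' @export
calibrate_censoring <- function(scenario, target = scenario$target_censoring,
                                n_mc = 20000, calibration_seed = 20220101) {
  if (target <= 0.05 || target >= 0.95) {
    stop_bad_arg("`target` censoring must lie in (0.05, 0.95).")
  }
  D <- with_seed(calibration_seed, draw_event_times(scenario, n_mc)$D)
  rate <- function(cc) mean(pmin(D / cc, 1)) - target
  lo <- min(D) / 2; hi <- max(D) * 2
  for (i in 1:30) {
    if (rate(lo) > 0 && rate(hi) < 0) break
    lo <- lo / 4; hi <- hi * 4
  }
  if (!(rate(lo) > 0 && rate(hi) < 0)) {
    abort("could not bracket the censoring target", class = "ahazmed_bad_arg")
  }
  cc <- uniroot(rate, c(lo, hi), tol = 1e-8)$root
  if (abs(rate(cc)) > 0.005) {
    abort("censoring calibration did not reach the 0.5% tolerance")
  }
  cc
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate one dataset from a simulation scenario
#'
#' Draws exposure, covariates, the full n x p mediator matrix and
#' event/censoring times under the scenario (see [sim_scenario()]), all
#' from the given seed.  The returned `survmed_data` carries attributes
#' `truth` (true-mediator indices), `censor_upper`, `censoring_rate`
#' (realized) and `n_redraws` (subjects redrawn because the cumulative
#' hazard came out negative at the solution — effectively zero at the
#' design's parameter magnitudes).
#'
#' @param scenario A [sim_scenario()].
#' @param seed Seed for this dataset; defaults to the scenario seed.
#' @return A `survmed_data` object with truth attributes.
#' @export
simulate_survmed <- function(scenario, seed = scenario$seed) {
  scn <- scenario
  if (!inherits(scn, "sim_scenario")) stop_bad_arg("`scenario` must be a sim_scenario.")
  cc <- scn$censor_upper %||% calibrate_censoring(scn)
  set.seed(seed)
  n <- scn$n; p <- scn$p
  X <- rbinom(n, 1, scn$exposure_prob)
  Z1 <- rbinom(n, 1, 0.3)
  Z2 <- runif(n)
  ck <- runif(p, scn$intercept_range[1], scn$intercept_range[2])
  Emat <- matrix(rnorm(n * p), n, p)
  if (scn$mediator_correlation > 0) {
    g <- rnorm(n)
    Emat <- sqrt(scn$mediator_correlation) * g +
      sqrt(1 - scn$mediator_correlation) * Emat
  }
  lp_z <- scn$theta_true[1] * Z1 + scn$theta_true[2] * Z2
  M <- Emat
  M <- M + matrix(ck, n, p, byrow = TRUE)
  nz_a <- which(scn$alpha_true != 0)
  if (length(nz_a)) {
    M[, nz_a] <- M[, nz_a] + outer(X, scn$alpha_true[nz_a])
  }
  M <- M + lp_z

  nz_b <- which(scn$beta_true != 0)
  eta <- scn$gamma_true * X + lp_z +
    if (length(nz_b)) drop(M[, nz_b, drop = FALSE] %*% scn$beta_true[nz_b]) else 0
  E <- rexp(n)
  s <- scn$baseline_slope
  D <- (-eta + sqrt(eta^2 + 2 * s * E)) / s

  # redraw policy for a negative cumulative hazard at the solution; by
  # construction Lambda(D) equals the Exp(1) draw, so this never fires under
  # the design's magnitudes, but the accounting is kept.
  bad <- which((s / 2) * D^2 + eta * D < 0)
  n_redraws <- 0L
  while (length(bad)) {
    n_redraws <- n_redraws + length(bad)
    Emat_b <- matrix(rnorm(length(bad) * p), length(bad), p)
    M[bad, ] <- Emat_b + matrix(ck, length(bad), p, byrow = TRUE) + lp_z[bad]
    if (length(nz_a)) M[bad, nz_a] <- M[bad, nz_a] + outer(X[bad], scn$alpha_true[nz_a])
    eta[bad] <- scn$gamma_true * X[bad] + lp_z[bad] +
      drop(M[bad, nz_b, drop = FALSE] %*% scn$beta_true[nz_b])
    E[bad] <- rexp(length(bad))
    D[bad] <- (-eta[bad] + sqrt(eta[bad]^2 + 2 * s * E[bad])) / s
    bad <- bad[(s / 2) * D[bad]^2 + eta[bad] * D[bad] < 0]
  }
  if (n_redraws > 0.01 * n) {
    warn(sprintf("%d subject redraws (> 1%% of n) due to negative cumulative hazard",
                 n_redraws))
  }

  C <- runif(n, 0, cc)
  time <- pmin(D, C)
  status <- as.double(D <= C)
  out <- new_survmed_data(
    time = time, status = status, exposure = X,
    covariates = cbind(Z1 = Z1, Z2 = Z2), mediators = M,
    mediator_names = paste0("M", seq_len(p))
  )
  attr(out, "truth") <- scn$truth
  attr(out, "censor_upper") <- cc
  attr(out, "censoring_rate") <- mean(status == 0)
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Score a selected mediator set against the simulation truth
#'
#' @param selected Integer indices declared mediators.
#' @param truth Integer indices of true mediators (both paths nonzero).
#' @param p Total number of candidates.
#' @return A one-row tibble: `tpr` (share of truth recovered), `fp`
#'   (false-selection count), `fdp` (false share of the selection, 0 when
#'   nothing is selected).
#' @examples
#' score_selection(c(1, 2, 9), 1:4, p = 100)
#' @export
score_selection <- function(selected, truth, p) {
  if (!length(truth)) {
    abort("empty truth set: scenario misconfigured", class = "ahazmed_bad_arg")
  }
  selected <- unique(as.integer(selected))
  if (length(selected) && (min(selected) < 1 || max(selected) > p)) {
    stop_bad_arg("`selected` indices out of 1..p.")
  }
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  tibble(tpr = tp / length(truth), fp = fp,
         fdp = if (length(selected)) fp / length(selected) else 0)
}

#' Replicated simulation study of the mediation procedure
#'
#' Repeats dataset generation and analysis under one scenario and
#' aggregates selection accuracy (TPR, FP count, FDP — averaged over
#' replicates) and per-mediator indirect-effect estimation quality (mean
#' estimate, 95% CI coverage, empirical and mean estimated SE — over the
#' replicates in which the mediator entered the selected subset S2).  Both
#' BH and BY significance lines are scored in one pass; the naive and
#' joint-significance baselines can be run on the same replicates.
#'
#' @param scenario A [sim_scenario()].
#' @param n_replicates Number of replicates.
#' @param methods Subset of `c("proposed", "naive", "joint")`.
#' @param level Significance level on the adjusted p values.
#' @param track_mediators Indices whose estimation metrics are tabulated
#'   (default the first 8 design mediators).
#' @param quiet Suppress the per-replicate progress line.
#' @param ... Extra arguments passed to [mediate_ahaz()] (e.g. `screen_stat`,
#'   `nlambda`).
#' @return A list of class `sim_study`: `selection` (tibble: method,
#'   adjust, tpr, fp, fdp, n_replicates), `estimation` (tibble: mediator
#'   index/name, true_ie, n_selected, est_mean, coverage, emp_se,
#'   est_se_mean — proposed method), `replicates` (long per-replicate
#'   tibble), `failures`.
#' @export
run_sim_study <- function(scenario, n_replicates = 100,
                          methods = "proposed", level = 0.05,
                          track_mediators = 1:8, quiet = TRUE, ...) {
  if (n_replicates < 1) stop_bad_arg("`n_replicates` must be at least 1.")
  if (!length(scenario$truth)) {
    abort("scenario misconfigured: no mediator has both paths nonzero, nothing to score",
          class = "ahazmed_bad_arg")
  }
  methods <- match.arg(methods, c("proposed", "naive", "joint"), several.ok = TRUE)
  scn <- scenario
  cc <- scn$censor_upper %||% calibrate_censoring(scn)
  scn$censor_upper <- cc
  truth <- scn$truth
  track_mediators <- track_mediators[track_mediators <= scn$p]

  sel_rows <- list()
  est_rows <- list()
  failures <- character()
  for (r in seq_len(n_replicates)) {
    seed_r <- derive_seed(scn$seed, r)
    res <- tryCatch(
      one_replicate(scn, seed_r, methods, level, track_mediators, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r, conditionMessage(res)))
      next
    }
    res$selection$replicate <- r
    sel_rows[[length(sel_rows) + 1L]] <- res$selection
    if (!is.null(res$estimation)) {
      res$estimation$replicate <- r
      est_rows[[length(est_rows) + 1L]] <- res$estimation
    }
    if (!quiet) inform(sprintf("replicate %d/%d done", r, n_replicates))
  }
  if (length(failures) > 0.05 * n_replicates) {
    abort(paste0("more than 5% of replicates failed:\n",
                 paste(utils::head(failures, 5), collapse = "\n")))
  }
  per_rep <- dplyr::bind_rows(sel_rows)
  selection <- per_rep |>
    dplyr::group_by(.data$method, .data$adjust) |>
    dplyr::summarise(tpr = mean(.data$tpr), fp = mean(.data$fp),
                     fdp = mean(.data$fdp),
                     n_replicates = dplyr::n(), .groups = "drop")

  estimation <- NULL
  if (length(est_rows)) {
    true_ie <- scn$alpha_true * scn$beta_true
    estimation <- dplyr::bind_rows(est_rows) |>
      dplyr::group_by(.data$index) |>
      dplyr::summarise(
        n_selected = dplyr::n(),
        est_mean = mean(.data$ie_hat),
        coverage = mean(.data$covered),
        emp_se = if (dplyr::n() > 1) sd(.data$ie_hat) else NA_real_,
        est_se_mean = mean(.data$sobel_se), .groups = "drop"
      ) |>
      dplyr::mutate(mediator = paste0("M", .data$index),
                    true_ie = true_ie[.data$index], .before = 1)
  }

  structure(list(selection = selection, estimation = estimation,
                 replicates = per_rep, failures = failures,
                 scenario = scn, n_replicates = n_replicates,
                 methods = methods),
            class = "sim_study")
}

one_replicate <- function(scn, seed_r, methods, level, track_mediators, ...) {
  dat <- simulate_survmed(scn, seed = seed_r)
  truth <- scn$truth
  p <- scn$p
  sel_rows <- list()
  est <- NULL

  score_both <- function(rec, method) {
    purrr::map(c("bh", "by"), function(adj) {
      padj <- if (adj == "bh") rec$p_bh else rec$p_by
      sig <- rec$index[!is.na(padj) & padj < level]
      cbind(tibble(method = method, adjust = adj), score_selection(sig, truth, p))
    }) |> dplyr::bind_rows()
  }

  if ("proposed" %in% methods || "joint" %in% methods) {
    fit <- mediate_ahaz(dat, level = level, seed = seed_r, ...)
    rec <- fit$records
    if ("proposed" %in% methods) {
      sel_rows$proposed <- score_both(rec, "proposed")
      keep <- rec$index %in% track_mediators
      if (any(keep)) {
        true_ie <- (scn$alpha_true * scn$beta_true)[rec$index[keep]]
        est <- tibble(index = rec$index[keep], ie_hat = rec$ie_hat[keep],
                      sobel_se = rec$sobel_se[keep],
                      covered = rec$ci_low[keep] <= true_ie &
                        true_ie <= rec$ci_high[keep])
      }
    }
    if ("joint" %in% methods) {
      # same S2; re-test with the max-p combination
      rec_j <- refit_and_test(dat, fit$scad$selected$index, level = level,
                              test = "joint")
      sel_rows$joint <- score_both(rec_j, "joint")
    }
  }
  if ("naive" %in% methods) {
    rec_n <- naive_mediate_ahaz(dat, level = level)
    sel_rows$naive <- score_both(rec_n, "naive")
  }
  list(selection = dplyr::bind_rows(sel_rows), estimation = est)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d replicates, n = %d, p = %d, target censoring %.0f%%\n",
              x$n_replicates, x$scenario$n, x$scenario$p,
              100 * x$scenario$target_censoring))
  print(x$selection, ...)
  if (!is.null(x$estimation)) {
    cat("indirect-effect estimation (proposed, over selecting replicates):\n")
    print(x$estimation, ...)
  }
  invisible(x)
}
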