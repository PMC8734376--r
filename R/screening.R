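#' Screened-subset size for sure independence screening
#'
#' The target number of mediators retained by the screening step,
#' \eqn{d = [2n/\log(n)]} with natural log and rounding half up — twice the
#' classical \eqn{[n/\log n]} choice, because a mediator must survive on both
#' the exposure side and the outcome side of the pathway.
#'
#' @param n Number of subjects (>= 3).
#' @return Integer subset size, at least 1.
#' @examples
#' sis_subset_size(833)  # 248
#' @export
sis_subset_size <- function(n) {
  assert_scalar_number(n, "n", positive = TRUE)
  if (n < 3) stop_bad_arg("`n` must be at least 3 for the screening-size formula.")
  max(1L, as.integer(round_half_up(2 * n / log(n))))
}

#' Sure independence screening of candidate mediators
#'
#' Ranks the p mediators by a marginal utility and keeps the top
#' `d = sis_subset_size(n)` (subset S1).  The default utility is the raw
#' Pearson correlation between the exposure and each mediator column;
#' `statistic = "marginal_hazard"` instead uses the standardized coefficient
#' of each mediator from its marginal additive-hazards fit (outcome side),
#' available for sensitivity analysis.
#'
#' @param data A `survmed_data` object or a data frame (with column mapping
#'   in `...`).
#' @param statistic Screening utility; see Details.
#' @param d Subset size; defaults to `sis_subset_size(n)` and is capped at p.
#' @param ... Column mapping passed to [survmed_data()].
#' @return A tibble of class `sis_screen` with one row per mediator:
#'   `mediator`, `index`, `score`, `rank` (by descending absolute score,
#'   ties broken by ascending index), `selected`.  Attributes `d` and
#'   `statistic` record the configuration; `attr(x, "selected_indices")`
#'   gives S1 in rank order.
#' @examples
#' sim <- simulate_survmed(sim_scenario(n = 120, p = 30, censor_upper = 2))
#' scr <- sis_screen(sim)
#' head(dplyr::arrange(scr, rank))
#' @export
sis_screen <- function(data,
                       statistic = c("exposure_correlation", "marginal_hazard"),
                       d = NULL, ...) {
  data <- as_survmed_data(data, ...)
  statistic <- match.arg(statistic)
  n <- length(data$time)
  p <- ncol(data$mediators)
  if (p < 1L) stop_bad_arg("No mediators to screen.")
  d <- if (is.null(d)) sis_subset_size(n) else as.integer(d)
  if (d < 1L) stop_bad_arg("`d` must be at least 1.")
  d <- min(d, p)

  if (statistic == "exposure_correlation") {
    x <- data$exposure
    if (sd(x) == 0) stop_bad_arg("Exposure is constant; correlation screening undefined.")
    xc <- x - mean(x)
    M <- data$mediators
    cov_xm <- drop(crossprod(xc, M)) / (n - 1)
    sd_m <- sqrt(pmax(colSums(M^2) - n * colMeans(M)^2, 0) / (n - 1))
    score <- rep(0, p)
    ok <- sd_m > 0
    score[ok] <- cov_xm[ok] / (sd(x) * sd_m[ok])
    if (any(!ok)) {
      warn(sprintf("%d mediator column(s) have zero variance; score set to 0.",
                   sum(!ok)))
    }
  } else {
    mf <- marginal_ahaz_all(data)
    score <- mf$beta_hat / mf$beta_se
    bad <- !is.finite(score)
    if (any(bad)) {
      warn(sprintf("%d mediator column(s) gave a degenerate marginal fit; score set to 0.",
                   sum(bad)))
      score[bad] <- 0
    }
  }

  rk <- order(-abs(score), seq_len(p))          # ties by ascending index
  rank_of <- integer(p); rank_of[rk] <- seq_len(p)
  out <- tibble(mediator = data$mediator_names, index = seq_len(p),
                score = score, rank = rank_of, selected = rank_of <= d)
  structure(out, class = c("sis_screen", class(out)),
            d = d, statistic = statistic, selected_indices = rk[seq_len(d)])
}

#' Indices of the screened subset S1, in rank order
#' @param x A `sis_screen` object.
#' @export
screened_indices <- function(x) {
  if (!inherits(x, "sis_screen")) stop_bad_arg("`x` must be a `sis_screen` object.")
  attr(x, "selected_indices")
}
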