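#' Plot screening scores
#'
#' Absolute screening utility against mediator index, with the retained
#' subset S1 highlighted and the implied selection threshold drawn.
#'
#' @param object A [sis_screen()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sis_screen
#' @export
autoplot.sis_screen <- function(object, ...) {
  df <- as_tibble(object)
  thr <- min(abs(df$score[df$selected]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = abs(.data$score),
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "mediator index", y = "|screening score|",
                  colour = "in S1",
                  title = sprintf("Sure independence screening (d = %d)",
                                  attr(object, "d"))) +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation curve of the SCAD path
#'
#' Held-out quadratic loss against log lambda, annotated with the number of
#' selected mediators along the path and the chosen lambda.
#'
#' @param object A [cv_ahaz_scad()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_ahaz_scad
#' @export
autoplot.cv_ahaz_scad <- function(object, ...) {
  cv <- object$cv_curve
  ggplot2::ggplot(cv, ggplot2::aes(x = log(.data$lambda), y = .data$cv_loss)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n_selected)) +
    ggplot2::geom_vline(xintercept = log(object$lambda_star), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "cross-validated loss",
                  colour = "|S2|",
                  title = sprintf("5-fold CV, lambda* = %.3g", object$lambda_star)) +
    ggplot2::theme_minimal()
}

#' Forest plot of estimated indirect effects
#'
#' One row per tested mediator: the Sobel point estimate with its Wald
#' interval, significant mediators (on the chosen adjustment) highlighted.
#'
#' @param object A [mediate_ahaz()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mediate_ahaz
#' @export
autoplot.mediate_ahaz <- function(object, ...) {
  rec <- tidy(object)
  if (!nrow(rec)) {
    rlang::abort("nothing to plot: no mediators were selected")
  }
  rec$mediator <- factor(rec$mediator, levels = rec$mediator[order(rec$ie_hat)])
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$ie_hat, y = .data$mediator,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#0072B2")) +
    ggplot2::labs(x = "indirect effect (hazard difference per exposure contrast)",
                  y = NULL, colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot selection accuracy across study scenarios
#'
#' TPR, FP and FDP of each method/adjustment combination in a replicated
#' simulation study.
#'
#' @param object A [run_sim_study()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_study
#' @export
autoplot.sim_study <- function(object, ...) {
  long <- tidyr::pivot_longer(object$selection, c("tpr", "fp", "fdp"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = toupper(.data$adjust), y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ toupper(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "p-value adjustment", y = NULL, fill = "method",
                  title = sprintf("Selection accuracy over %d replicates",
                                  object$n_replicates)) +
    ggplot2::theme_minimal()
}
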