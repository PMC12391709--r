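#' Plot per-trigger detection performance
#'
#' Bar chart of per-trigger positive predictive values colored by utility
#' class, ordered by trigger id.
#'
#' @param object An `ade_metrics` report from [build_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ade_metrics <- function(object, ...) {
  df <- object$per_trigger
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trigger_id, y = .data$ppv,
                                   fill = .data$utility)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$overall_ppv, linetype = "dashed") +
    ggplot2::labs(x = "trigger", y = "PPV (%)", fill = "utility",
                  subtitle = paste0("overall PPV ", object$overall_ppv, "%")) +
    ggplot2::theme_minimal()
}

#' Plot screening hit counts per trigger
#'
#' @param object An `ade_screening` from [screen_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ade_screening <- function(object, ...) {
  df <- dplyr::count(object$hits, .data$trigger_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trigger_id, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "trigger", y = "flagged admissions") +
    ggplot2::theme_minimal()
}

#' Forest plot of ADE risk-factor odds ratios
#'
#' Odds ratios with Wald 95% confidence intervals per non-reference covariate
#' level (the intercept is omitted).
#'
#' @param object An `ade_logistic` from [fit_logistic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ade_logistic <- function(object, ...) {
  co <- object$coefficients |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(
      lo = exp(log(.data$odds_ratio) - 1.96 * .data$std_error),
      hi = exp(log(.data$odds_ratio) + 1.96 * .data$std_error))
  ggplot2::ggplot(co, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Delphi item statistics against the retention cut-offs
#'
#' Mj versus Vj per item, with the cut-off lines and the retain / discuss /
#' drop decision as color.
#'
#' @param decisions Output of [select_items()].
#' @param cutoffs The [delphi_cutoffs()] used for the decisions.
#' @return A ggplot object.
#' @export
plot_delphi_items <- function(decisions, cutoffs) {
  ggplot2::ggplot(decisions,
                  ggplot2::aes(x = .data$Mj, y = .data$Vj,
                               color = .data$decision)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = cutoffs$Mj_cut, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cutoffs$Vj_cut, linetype = "dashed") +
    ggplot2::labs(x = "mean importance score (Mj)",
                  y = "coefficient of variation (Vj)") +
    ggplot2::theme_minimal()
}
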