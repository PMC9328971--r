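#' Plot methods for pipeline results
#'
#' `autoplot()` methods render the main result types as ggplot2 figures:
#' step-style Kaplan-Meier curves per risk group, the time-dependent ROC
#' curve with its AUC in the subtitle, the decision-curve net-benefit
#' sweep against the treat-all/treat-none references, and the AIC profile
#' over candidate risk-score cutoffs with the chosen cutoff marked.
#'
#' @param object A `km_curve`, `td_roc`, `net_benefit`, or `aic_cutoff`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ferropair-autoplot
NULL

#' @rdname ferropair-autoplot
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::distinct(tibble(group = object$group, time = 0, survival = 1)),
    tibble(group = object$group, time = object$time, survival = object$survival)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}

#' @rdname ferropair-autoplot
#' @export
autoplot.td_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(1 - .data$specificity,
                                       .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      subtitle = sprintf("horizon = %.0f, AUC = %.3f",
                         attr(object, "horizon"), attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname ferropair-autoplot
#' @export
autoplot.net_benefit <- function(object, ...) {
  df <- tidyr::pivot_longer(object, -"threshold",
                            names_to = "strategy", values_to = "net_benefit")
  df$strategy <- dplyr::recode(df$strategy, nb_model = "model",
                               nb_all = "treat all", nb_none = "treat none")
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$net_benefit,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit") +
    ggplot2::theme_minimal()
}

#' @rdname ferropair-autoplot
#' @export
autoplot.aic_cutoff <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$threshold, .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "risk-score cutoff", y = "Cox model AIC") +
    ggplot2::theme_minimal()
}
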