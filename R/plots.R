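## ggplot2 graphics for the main result types.

#' Plot a per-landmark accuracy table
#'
#' Point-range plot of per-landmark mean radial errors with their 95%
#' confidence intervals, in tracing order, with the conventional 2 mm
#' clinical-acceptability threshold marked.
#'
#' @param object A `ceph_accuracy` table from [summarize_accuracy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceph_accuracy <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$landmark <- factor(df$landmark, levels = rev(landmark_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mre_mean, y = .data$landmark)) +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::labs(x = "Mean radial error (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot successful detection rates per landmark
#'
#' @param accuracy A `ceph_accuracy` table from [summarize_accuracy()].
#' @return A ggplot object with one column facet per threshold.
#' @export
plot_sdr <- function(accuracy) {
  df <- tibble::as_tibble(accuracy) |>
    tidyr::pivot_longer(dplyr::starts_with("sdr_"),
                        names_to = "threshold", values_to = "sdr")
  df$threshold <- factor(
    df$threshold,
    levels = unique(df$threshold),
    labels = sub("sdr_", "", unique(df$threshold))
  )
  df$landmark <- factor(df$landmark, levels = rev(landmark_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sdr, y = .data$landmark)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~threshold, nrow = 1) +
    ggplot2::labs(x = "Successful detection rate (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fixed-effect estimates of a mixed-model fit
#'
#' Estimates with Wald 95% confidence intervals, excluding the intercept.
#'
#' @param object A `ceph_lme` fit from [fit_lme()] or [select_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceph_lme <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = sprintf("Effect on %s", object$response), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
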