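# ggplot2 displays for each result type.

#' @describeIn fit_spread_model Observed vs predicted log10 pathology per
#'   region, faceted by timepoint, with the identity-free least-squares
#'   trend.
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_fit <- function(object, ...) {
  df <- object$detail |> dplyr::filter(.data$used)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~mpi, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "predicted log10 % area occupied",
      y = "observed log10 % area occupied",
      title = sprintf("%s spread model, pooled r = %.3f",
                      object$model, object$r_pooled)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn seed_specificity_test Histogram of null fit correlations
#'   with the observed true-seed fit marked.
#' @param object A `seed_null`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.seed_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_r,
                        colour = "black", linewidth = 0.9) +
    ggplot2::labs(
      x = "Pearson r (distance-matched random seeds)",
      y = "count",
      title = sprintf("Seed specificity: observed r = %.3f, p = %.4g",
                      object$observed_r, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn crossval_compare Distributions of held-out Pearson r per
#'   model.
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.model_comparison <- function(object, ...) {
  df <- object$draws |>
    dplyr::mutate(model = factor(.data$model, levels = object$models))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$r_test)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(
      x = NULL, y = "held-out Pearson r",
      title = sprintf("Cross-validated model comparison (%d iterations)",
                      object$n_iter)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn bootstrap_group Density of each bootstrapped statistic.
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.bootstrap_result <- function(object, ...) {
  df <- object$draws |>
    tidyr::pivot_longer(-"resample", names_to = "statistic",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey40") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "density",
      title = sprintf("Bootstrap distributions: %s (%d resamples)",
                      object$group_label, object$n_boot)
    ) +
    ggplot2::theme_minimal()
}

#' Plot regional effect sizes with significance flags
#'
#' Dot-and-interval display of the output of [regional_comparison()],
#' one panel per hemisphere-timepoint, regions ordered by effect size and
#' colored by the SGPV significance call.
#'
#' @param effects Tibble from [regional_comparison()].
#' @param top_n Show only the `top_n` regions by absolute effect
#'   (default all).
#' @return A ggplot object.
#' @export
plot_regional_effects <- function(effects, top_n = Inf) {
  df <- effects |>
    dplyr::filter(is.na(.data$reason)) |>
    dplyr::mutate(call = dplyr::if_else(.data$significant,
                                        "significant (SGPV = 0)",
                                        "not significant"))
  if (is.finite(top_n)) {
    df <- df |>
      dplyr::slice_max(abs(.data$effect), n = top_n, with_ties = FALSE)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$effect,
    y = stats::reorder(paste(.data$region, .data$hemisphere),
                       .data$effect),
    colour = .data$call
  )) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_colour_manual(values = c(
      "significant (SGPV = 0)" = "#b2182b",
      "not significant" = "grey50"
    )) +
    ggplot2::facet_wrap(~mpi, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "effect (rank scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
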