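#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a population field as a space-time heatmap
#'
#' @param object A [population_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot population_field
#' @export
autoplot.population_field <- function(object, ...) {
  df <- tidy.population_field(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$s,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time", y = "structural variable s",
                  fill = "density") +
    ggplot2::theme_minimal()
}

#' Plot a weak-form fit: coefficients and selection loss
#'
#' Shows the recovered coefficients by library column, coloured by role,
#' with unselected columns at zero.
#'
#' @param object A `wsindy_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wsindy_fit
#' @export
autoplot.wsindy_fit <- function(object, ...) {
  df <- tidy.wsindy_fit(object)
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate,
                                   fill = .data$role,
                                   alpha = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the MSTLS selection-loss curve
#'
#' @param fit A `wsindy_fit` or the result of [mstls()].
#' @return A ggplot of the selection loss against the sparsity parameter,
#'   with the chosen \eqn{\lambda^\star} marked.
#' @export
plot_loss_curve <- function(fit) {
  ggplot2::ggplot(fit$loss_curve,
                  ggplot2::aes(x = .data$lambda, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = fit$lambda_star, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "selection loss") +
    ggplot2::theme_minimal()
}

#' Plot a noise sweep: mean metrics against the noise level
#'
#' @param sweep A tibble from [run_noise_sweep()].
#' @return A ggplot of mean TPR and prediction error per noise level.
#' @export
plot_noise_sweep <- function(sweep) {
  long <- sweep |>
    dplyr::group_by(.data$snr) |>
    dplyr::summarise(
      TPR = mean(.data$tpr),
      E_p = mean(.data$e_p[is.finite(.data$e_p)]),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"snr", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snr, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(sigma[NR]), y = NULL) +
    ggplot2::theme_minimal()
}
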