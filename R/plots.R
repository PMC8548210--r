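#' Plot an enrichment result table
#'
#' Bar plot of fold over the permutation null per family (or pairing),
#' annotated with the empirical probability.
#'
#' @param x Enrichment tibble from [repeat_family_enrichment()] or
#'   stacked rows from [proximity_enrichment_test()].
#' @param label Column naming the bars (default `"family"`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x, label = "family") {
  ggplot2::ggplot(x, ggplot2::aes(
    x = stats::reorder(.data[[label]], -.data$fold), y = .data$fold
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p = %.3g", .data$p_emp)
    ), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "fold over permutation null") +
    ggplot2::theme_minimal()
}

#' MA-style plot of differential results
#'
#' @param x Tibble from [differential_regions()] or [call_degs()].
#' @return A ggplot object.
#' @export
plot_differential <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(
    x = log2((.data$mean_a + .data$mean_b) / 2 + 0.25),
    y = .data$log2_fold_change, colour = .data$direction
  )) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "navy", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 mean signal", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot a coverage metaprofile
#'
#' @param profile Numeric vector from [region_metaprofile()].
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(profile) {
  df <- tibble::tibble(bin = seq_along(profile), coverage = profile)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$coverage)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "bin", y = "mean coverage") +
    ggplot2::theme_minimal()
}

#' Plot a Hill fit over its data
#'
#' Points are the measured responses; the line is the fitted binding
#' (or inhibition) law on a log-spaced concentration grid.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(concentration_nM = exp(seq(
    log(min(d$concentration_nM)), log(max(d$concentration_nM)),
    length.out = 200
  )))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(.data$concentration_nM,
                                  .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (nM)",
      y = if (object$model == "binding") "fraction bound" else {
        "remodeling efficiency (% of control)"
      },
      subtitle = sprintf("Kd = %.3g nM, h = %.2f",
                         object$coefficients["Kd"],
                         object$coefficients["h"])
    ) +
    ggplot2::theme_minimal()
}
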