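#' Plot a vesicle cargo census
#'
#' Bar chart of the dual-cargo / channel-1-only / channel-2-only proportions.
#'
#' @param object A `vesicle_census` (from [vesicle_census()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vesicle_census
#' @export
autoplot.vesicle_census <- function(object, ...) {
  df <- tibble::tibble(
    class = factor(c("both", "ch1_only", "ch2_only"),
                   levels = c("both", "ch1_only", "ch2_only")),
    proportion = c(object$p_both, object$p_ch1_only, object$p_ch2_only))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "cargo class", y = "proportion of vesicles",
                  title = sprintf("Cargo census (n = %d)", object$n_total)) +
    ggplot2::theme_minimal()
}

#' Plot a two-group comparison
#'
#' Group means with standard-error bars and the significance star code.
#'
#' @param object A `group_comparison` (from [group_compare()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey55", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::annotate("text", x = 1.5, y = max(df$mean + df$se) * 1.05,
                      label = object$star_code) +
    ggplot2::labs(y = "mean ± s.e.", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot detected vesicles over a channel
#'
#' Shows one channel as a raster with detection centroids circled, scaled to
#' the measured equivalent diameters.
#'
#' @param img An [mc_image()].
#' @param detections A [detect_vesicles()] tibble.
#' @param channel Channel to display.
#' @return A ggplot object.
#' @export
plot_detections <- function(img, detections, channel = 1) {
  mat <- get_channel(img, channel)
  df <- tibble::tibble(x = rep(seq_len(ncol(mat)) - 1, each = nrow(mat)),
                       y = rep(seq_len(nrow(mat)) - 1, times = ncol(mat)),
                       intensity = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = detections, shape = 1, colour = "red",
                        ggplot2::aes(size = .data$diameter_um)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Box plot of a measurement report metric
#'
#' Reproduces the standard per-group box plot (median, quartiles, whiskers at
#' 1.5 IQR) from a [build_report()] summary.
#'
#' @param report A `measurement_report`.
#' @param metric Metric name to plot (default the first).
#' @return A ggplot object.
#' @export
plot_report_metric <- function(report, metric = NULL) {
  s <- report$summary
  metric <- metric %||% s$metric[1]
  s <- s[s$metric == metric, ]
  grp <- setdiff(names(s), c("metric", "n", "mean", "sd", "se", "median",
                             "q1", "q3", "whisker_low", "whisker_high"))[1]
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[grp]])) +
    ggplot2::geom_boxplot(stat = "identity",
                          ggplot2::aes(lower = .data$q1, upper = .data$q3,
                                       middle = .data$median,
                                       ymin = .data$whisker_low,
                                       ymax = .data$whisker_high)) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal()
}
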