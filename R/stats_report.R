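#' Two-group comparison by pooled-variance Student's t-test
#'
#' The group-comparison procedure used throughout the measurement reports: an
#' unpaired two-tailed Student's t-test with pooled variance
#' (df = n_a + n_b - 2), per-group means with standard errors
#' (s.e. = s.d. / sqrt(n)), the percent difference of group B relative to
#' group A, and a significance star code (`*` p < 0.05, `**` 0.001 < p <
#' 0.01, `***` p < 0.001, `ns` otherwise; p in [0.01, 0.05) earns `*`).
#' Welch's unequal-variance test is available via `var_equal = FALSE`.
#' Identical degenerate samples (zero pooled variance, equal means) give
#' t = 0, p = 1; zero variance with unequal means is flagged degenerate.
#'
#' @param a,b Numeric samples, each with at least 2 finite values.
#' @param labels Character length-2 group labels.
#' @param var_equal Pool the variances (classic Student's t, default TRUE).
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' gc <- group_compare(c(1, 2, 3), c(2, 3, 4))
#' glance(gc)
#' @export
group_compare <- function(a, b, labels = c("A", "B"), var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  degenerate <- FALSE
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1,
                 parameter = c(df = length(a) + length(b) - 2))
    } else {
      tt <- list(statistic = c(t = Inf * sign(mean(a) - mean(b))), p.value = 0,
                 parameter = c(df = length(a) + length(b) - 2))
      degenerate <- TRUE
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  p <- tt$p.value
  structure(list(
    labels = labels,
    n = c(length(a), length(b)),
    means = c(mean(a), mean(b)),
    sds = c(stats::sd(a), stats::sd(b)),
    ses = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = p,
    star_code = significance_stars(p),
    percent_difference = if (mean(a) > 0) percent_difference(mean(a), mean(b)) else NA_real_,
    var_equal = var_equal,
    degenerate = degenerate
  ), class = "group_comparison")
}

#' Significance star code
#'
#' `***` for p < 0.001, `**` for 0.001 < p < 0.01, `*` for p < 0.05 (this
#' band includes [0.01, 0.05) and, by strict-inequality reading of the
#' printed thresholds, p exactly 0.001 or 0.01), `ns` otherwise.
#'
#' @param p P-value(s) in [0, 1].
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p > 0.001 & p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Percent difference of a mutant mean relative to a control mean
#'
#' `((mean_mut - mean_ctrl) / mean_ctrl) * 100`; positive means longer /
#' larger than control, negative a reduction.
#'
#' @param mean_ctrl Control (reference) mean, must be > 0.
#' @param mean_mut Comparison mean.
#' @return Signed percent difference.
#' @examples
#' percent_difference(1.0, 1.226) # 22.6
#' @export
percent_difference <- function(mean_ctrl, mean_mut) {
  if (any(mean_ctrl <= 0)) {
    stop("control mean must be positive for a percent difference", call. = FALSE)
  }
  (mean_mut - mean_ctrl) / mean_ctrl * 100
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d, mean %.4g +/- %.3g s.e.) vs %s (n=%d, mean %.4g +/- %.3g s.e.)\n",
              x$labels[1], x$n[1], x$means[1], x$ses[1],
              x$labels[2], x$n[2], x$means[2], x$ses[2]))
  cat(sprintf("  t = %.4f, df = %g, p = %.4g %s; percent difference %.3g%%\n",
              x$t_statistic, x$df, x$p_value, x$star_code,
              x$percent_difference))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: one row per group (`group, n, mean, sd, se`);
#'   `glance()`: a one-row tibble with the test results.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(group = x$labels, n = x$n, mean = x$means, sd = x$sds,
                 se = x$ses)
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(group_a = x$labels[1], group_b = x$labels[2],
                 n_a = x$n[1], n_b = x$n[2],
                 mean_a = x$means[1], mean_b = x$means[2],
                 se_a = x$ses[1], se_b = x$ses[2],
                 t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
                 star_code = x$star_code,
                 percent_difference = x$percent_difference,
                 degenerate = x$degenerate)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Assemble a measurement report with group summaries and comparisons
#'
#' Takes a tidy measurement table (one row per measured object) and produces
#' per-metric, per-group summaries (n, mean, s.d., s.e., and box-plot
#' statistics: median, quartiles, whiskers at 1.5 IQR) plus pairwise
#' pooled-t comparisons of every other group against the reference (first)
#' group. No multiple-testing correction is applied, matching the reporting
#' convention this mirrors; a note flags runs with more than 5 comparisons.
#'
#' @param measurements Data frame with a grouping column and one or more
#'   numeric metric columns.
#' @param group Name of the grouping column.
#' @param metrics Character vector of metric columns; defaults to all numeric
#'   columns except the group.
#' @param reference Reference group label; defaults to the first level.
#' @return A list of class `measurement_report` with tibbles `summary` and
#'   `comparisons`, and `n_comparisons_note`.
#' @export
build_report <- function(measurements, group, metrics = NULL, reference = NULL) {
  measurements <- tibble::as_tibble(measurements)
  if (!group %in% names(measurements)) {
    stop(sprintf("unknown group column '%s'", group), call. = FALSE)
  }
  if (nrow(measurements) == 0) {
    warning("empty measurement table; returning empty report")
    return(structure(list(summary = tibble::tibble(),
                          comparisons = tibble::tibble(),
                          n_comparisons_note = NULL),
                     class = "measurement_report"))
  }
  if (is.null(metrics)) {
    metrics <- names(measurements)[vapply(measurements, is.numeric, TRUE)]
    metrics <- setdiff(metrics, group)
  }
  missing <- setdiff(metrics, names(measurements))
  if (length(missing)) {
    stop(sprintf("unknown metric column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(measurements[, c(group, metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$metric, dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(is.finite(.data$value))),
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      whisker_low = boxplot_whisker(.data$value, "low"),
      whisker_high = boxplot_whisker(.data$value, "high"),
      .groups = "drop")

  groups <- unique(as.character(measurements[[group]]))
  reference <- reference %||% groups[1]
  if (!reference %in% groups) {
    stop(sprintf("unknown reference group '%s'", reference), call. = FALSE)
  }
  others <- setdiff(groups, reference)
  comparisons <- purrr::map_dfr(metrics, function(mt) {
    purrr::map_dfr(others, function(gb) {
      a <- measurements[[mt]][measurements[[group]] == reference]
      b <- measurements[[mt]][measurements[[group]] == gb]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(metric = mt, group_a = reference, group_b = gb,
                              n_a = length(a), n_b = length(b)))
      }
      dplyr::mutate(glance(group_compare(a, b, labels = c(reference, gb))),
                    metric = mt, .before = 1)
    })
  })
  note <- if (nrow(comparisons) > 5) {
    sprintf("%d comparisons in one run; no multiple-testing correction applied",
            nrow(comparisons))
  }
  structure(list(summary = summary, comparisons = comparisons,
                 n_comparisons_note = note),
            class = "measurement_report")
}

boxplot_whisker <- function(v, side) {
  v <- v[is.finite(v)]
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  if (side == "low") min(v[v >= q[1] - 1.5 * iqr]) else max(v[v <= q[2] + 1.5 * iqr])
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report>\nsummary:\n")
  print(x$summary)
  if (nrow(x$comparisons %||% tibble::tibble())) {
    cat("comparisons:\n")
    print(x$comparisons)
  }
  if (!is.null(x$n_comparisons_note)) cat("note:", x$n_comparisons_note, "\n")
  invisible(x)
}

#' Write a measurement report to CSV and JSON
#'
#' @param report A `measurement_report`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir, stem = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(stem, "_summary.csv"))
  p2 <- file.path(dir, paste0(stem, "_comparisons.csv"))
  p3 <- file.path(dir, paste0(stem, ".json"))
  utils::write.csv(report$summary, p1, row.names = FALSE)
  utils::write.csv(report$comparisons, p2, row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            comparisons = report$comparisons,
                            note = report$n_comparisons_note),
                       p3, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(p1, p2, p3))
}
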