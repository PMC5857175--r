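#' Stacked composition or abundance bar plot
#'
#' Per-sample stacked bars of taxon proportions (relative view) or
#' copies-per-gram (absolute view). Pooling rare taxa first with
#' [pool_minor()] keeps the legend readable.
#'
#' @param table A long table with a `proportion`, `abundance` or `count`
#'   column.
#' @param log10_axis Use a log10 y axis (only sensible for absolute
#'   abundances plotted side by side rather than stacked).
#' @return A ggplot object.
#' @export
plot_composition <- function(table, log10_axis = FALSE) {
  value <- table_value_col(table)
  lab <- c(count = "reads", proportion = "relative abundance",
           abundance = "copies (g dry wt soil)^-1")[[value]]
  p <- ggplot2::ggplot(table, ggplot2::aes(
    x = .data$sample, y = .data[[value]], fill = .data$taxon
  )) +
    ggplot2::geom_col(position = if (log10_axis) "dodge" else "stack") +
    ggplot2::labs(x = NULL, y = lab, fill = NULL) +
    ggplot2::theme_minimal()
  if (log10_axis) p <- p + ggplot2::scale_y_log10()
  p
}

#' Heatmap matrix with clustered sample order
#'
#' Tile heatmap of log10(x+1) abundances with samples ordered by
#' [cluster_samples()]; the visual used to compare groupings under relative
#' versus absolute abundances.
#'
#' @param table A long abundance table.
#' @param ... Passed to [cluster_samples()].
#' @return A ggplot object.
#' @export
plot_abundance_heatmap <- function(table, ...) {
  hc <- cluster_samples(table, ...)
  value <- table_value_col(table)
  tbl <- mutate(table,
                sample = factor(.data$sample, levels = hc$labels[hc$order]))
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$sample, y = .data$taxon, fill = log10(.data[[value]] + 1)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10(x+1)") +
    ggplot2::theme_minimal()
}

#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$standards, ggplot2::aes(
    x = log10(.data$copies_per_ul), y = .data$ct
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 copies per uL", y = "Ct",
      title = sprintf("standard curve: slope %.3f, eff %.0f%%, R2 %.4f",
                      object$slope, 100 * object$efficiency, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot validation_fit
#' @export
autoplot.validation_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log10 estimate", y = "log10 expected",
      title = sprintf("slope %.3f, R2 %.4f (%s)", object$slope,
                      object$r2_centered,
                      if (object$through_origin) "through origin" else "with intercept")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot spike_validation
#' @export
autoplot.spike_validation <- function(object, ...) {
  fits <- filter(object$fits, .data$fit == "expected_vs_estimate",
                 .data$subset == "all")
  pts <- bind_rows(purrr::map(
    seq_len(nrow(fits)),
    ~ mutate(fits$result[[.x]]$data, region = fits$region[[.x]])
  ))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "log10 sequencing-derived copies per g",
                  y = "log10 expected (marker x copy ratio)") +
    ggplot2::theme_minimal()
}

#' @method autoplot discordance_summary
#' @export
autoplot.discordance_summary <- function(object, ...) {
  rec <- filter(object$records, !.data$undefined_pct)
  ggplot2::ggplot(rec, ggplot2::aes(
    x = .data$rel_change_pp, y = .data$abs_change_pct,
    colour = .data$trend_class
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "relative-abundance change (percentage points)",
                  y = "absolute-abundance change (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
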