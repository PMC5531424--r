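#' Plot methods for hspcfate results
#'
#' `autoplot()` methods return ggplot objects: the gap curve with its
#' reference-spread error bars, per-group correlation-burst edge counts, and
#' the mother-to-daughter phenotype transition matrix as a tile plot.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name hspcfate-plots
NULL

#' @rdname hspcfate-plots
#' @export
autoplot.gap_stat <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$gap - .data$se, ymax = .data$gap + .data$se
    )) +
    ggplot2::geom_vline(
      xintercept = object$k_selected, linetype = "dashed"
    ) +
    ggplot2::scale_x_continuous(breaks = tab$k) +
    ggplot2::labs(
      x = "number of clusters k", y = "gap(k)",
      title = sprintf("Gap statistic (selected k = %d)", object$k_selected)
    )
}

#' @rdname hspcfate-plots
#' @export
autoplot.correlation_networks <- function(object, ...) {
  counts <- object$counts
  grp_cols <- setdiff(
    names(counts), c("n_cells", "n_genes_used", "n_edges", "mean_r")
  )
  counts$group <- do.call(paste, c(counts[grp_cols], sep = " / "))
  ggplot2::ggplot(
    counts, ggplot2::aes(x = .data$group, y = .data$n_edges)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL,
      y = sprintf("gene pairs with r > %.2g", object$threshold),
      title = "Correlation-burst indicator"
    )
}

#' @rdname hspcfate-plots
#' @export
autoplot.phenotype_transition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$daughter, y = .data$mother, fill = .data$freq)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$freq), "", sprintf("%.2f", .data$freq))
    )) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue", na.value = "grey90", limits = c(0, 1)
    ) +
    ggplot2::labs(
      x = "daughter phenotype", y = "mother phenotype",
      fill = "frequency", title = "Phenotype inheritance"
    )
}

#' Scatter plot of the dynamic-phenotype space
#'
#' Roundness against switch frequency (point size = cycle length where
#' available), coloured by phenotype or sister-pair class if present.
#'
#' @param summaries Output of [summarize_cells()], optionally after
#'   [classify_phenotypes()].
#' @return A `ggplot`.
#' @export
plot_dynamics <- function(summaries) {
  aes_args <- ggplot2::aes(x = .data$roundness, y = .data$switch_freq)
  p <- ggplot2::ggplot(summaries, aes_args)
  if ("phenotype" %in% names(summaries)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$phenotype, size = .data$cycle_length_h),
      alpha = 0.7, na.rm = TRUE
    )
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(
    x = "roundness (fraction of lifetime round)",
    y = "switch frequency (/h)", size = "cycle length (h)"
  )
}

#' Plot a 2-D embedding of cells
#'
#' @param coords Output of [embed_2d()].
#' @param colour_by Optional metadata column to colour by (e.g.
#'   `"time_point"`, `"cluster"`).
#' @return A `ggplot`.
#' @export
plot_embedding <- function(coords, colour_by = NULL) {
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!is.null(colour_by) && colour_by %in% names(coords)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data[[colour_by]])), alpha = 0.8
    ) +
      ggplot2::labs(colour = colour_by)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(x = "dimension 1", y = "dimension 2")
}
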