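#' Manhattan plot of a window scan
#'
#' Plots window Z-scores (or the raw statistic) against cumulative genomic
#' position, chromosomes alternating in shade, with optional tail-threshold
#' guides.
#'
#' @param wins Window tibble with `chrom`, `start`, `end` and the plotted
#'   column.
#' @param y Column to plot (default `"z"` if present, else the statistic).
#' @param tail Optional tail fraction; draws the empirical quantile guides.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(wins, y = NULL, tail = NULL) {
  if (is.null(y)) {
    y <- intersect(c("z", "fst", "hp", "pi"), names(wins))[1]
  }
  offsets <- wins |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  dat <- wins |>
    dplyr::left_join(offsets, by = "chrom") |>
    dplyr::mutate(gpos = .data$offset + (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$gpos, .data[[y]],
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_x_continuous(
      breaks = offsets$offset + offsets$len / 2, labels = offsets$chrom
    ) +
    ggplot2::labs(x = NULL, y = y) +
    ggplot2::theme_minimal()
  if (!is.null(tail)) {
    q <- stats::quantile(dat[[y]], c(tail, 1 - tail), na.rm = TRUE)
    p <- p + ggplot2::geom_hline(yintercept = q, linetype = "dashed")
  }
  p
}

#' ROH length-class spectrum
#'
#' Bar chart of per-population ROH counts in the four length classes.
#'
#' @param roh_summary Count tibble from [categorize_roh()].
#' @return A ggplot object.
#' @export
plot_roh_spectrum <- function(roh_summary) {
  long <- tidyr::pivot_longer(
    roh_summary, cols = dplyr::all_of(roh_class_levels),
    names_to = "class", values_to = "n"
  ) |>
    dplyr::mutate(class = factor(.data$class, levels = roh_class_levels))
  ggplot2::ggplot(long, ggplot2::aes(.data$population, .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "ROH count", fill = "length class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
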