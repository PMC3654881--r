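#' Plot a weighted sequence as a probability heatmap
#'
#' One tile per stored (position, character) pair, filled by probability;
#' characters absent at a position (weight 0) are left blank.
#'
#' @param object A `wseq` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(example_wseq())
#' @method autoplot wseq
#' @export
autoplot.wseq <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$position,
    y = factor(.data$char, levels = rev(wseq_alphabet(object))),
    fill = .data$prob
  )) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "probability") +
    ggplot2::scale_x_continuous(breaks = scales_int_breaks(wseq_n(object))) +
    ggplot2::labs(x = "position", y = NULL,
      title = sprintf("Weighted sequence (n = %d)", wseq_n(object))) +
    ggplot2::theme_minimal()
}

#' Plot a repeat report as span segments
#'
#' Each run is drawn as a horizontal segment from its start to its end,
#' stacked by period and coloured by the weakest copy's probability.
#'
#' @param object A `wtr_repeats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(find_tandem_repeats(wseq_from_string("ATATATAT"), 0.5))
#' @method autoplot wtr_repeats
#' @export
autoplot.wtr_repeats <- function(object, ...) {
  tbl <- tibble::as_tibble(as.data.frame(object))
  if (nrow(tbl) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no tandem repeats") +
        ggplot2::theme_void()
    )
  }
  tbl <- dplyr::arrange(tbl, .data$period, .data$start)
  tbl$row <- seq_len(nrow(tbl))
  ggplot2::ggplot(tbl) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start - 0.5, xend = .data$end + 0.5,
        y = .data$row, yend = .data$row, colour = .data$min_copy_prob
      ),
      linewidth = 3
    ) +
    ggplot2::geom_text(
      ggplot2::aes(
        x = (.data$start + .data$end) / 2, y = .data$row,
        label = sprintf("%s x %d", .data$factor, .data$copies)
      ),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "min copy prob") +
    ggplot2::labs(x = "position", y = NULL, title = "Tandem repeats") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

scales_int_breaks <- function(n) {
  unique(round(seq(1, n, length.out = min(n, 10))))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
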