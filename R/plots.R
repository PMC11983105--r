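#' Plot Selict scores of classified sites along the genome
#'
#' Lollipop view of site scores coloured by classification.
#'
#' @param calls Classified calls from [classify_sites()].
#' @return A ggplot.
#' @export
plot_site_scores <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$pos, y = .data$selict_score,
                               colour = .data$classification)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = "Selict score",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Distribution of edit positions in protospacer coordinates
#'
#' Histogram of the protospacer position of each edit for sites with a
#' binding alignment (1 = PAM-distal, 20 = PAM-proximal; positions outside
#' 1..20 are out-of-protospacer edits). The editing window is shaded.
#'
#' @param calls Classified calls from [classify_sites()].
#' @param editing_window Window to shade (default 3:9).
#' @return A ggplot.
#' @export
plot_edit_positions <- function(calls, editing_window = 3:9) {
  df <- dplyr::filter(calls, !is.na(.data$protospacer_position))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protospacer_position)) +
    ggplot2::annotate("rect", xmin = min(editing_window) - 0.5,
                      xmax = max(editing_window) + 0.5,
                      ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "#255C99") +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = c(0.5, 20.5), linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "protospacer position of edit (1 = PAM-distal)",
                  y = "sites") +
    ggplot2::theme_minimal()
}

#' Per-position amplicon editing rates
#'
#' @param rates Tibble from [editing_rates()].
#' @return A ggplot of net rates, with unqualified positions greyed out.
#' @export
plot_editing_rates <- function(rates) {
  ggplot2::ggplot(rates,
                  ggplot2::aes(x = .data$offset, y = .data$net_rate,
                               fill = .data$passes_coverage)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#109648",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "amplicon position", y = "net editing rate (%)",
                  fill = ">=500x both samples") +
    ggplot2::theme_minimal()
}
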