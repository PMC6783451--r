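#' Manhattan plot of a sex-association scan
#'
#' @param scan A `sex_scan` tibble from [scan_genome()].
#' @param alpha Significance threshold drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_manhattan <- function(scan, alpha = 5e-8) {
  mt <- manhattan_table(scan)
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$cum_pos, y = .data$neg_log10_p,
                                   colour = factor(.data$scaffold_index %% 2))) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "cumulative position (bp)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sex_scan <- function(object, ...) plot_manhattan(object, ...)

#' Pairwise D' heatmap for a marker window
#'
#' Upper-triangle tile plot of the standard LD colouring: red for
#' `D' = 1` with `LOD >= 2`, blue for `D' = 1` with `LOD < 2`, white
#' otherwise.
#'
#' @param pairs Tibble from [scaffold_pairwise_ld()].
#' @return A ggplot.
#' @export
plot_ld_pairs <- function(pairs) {
  pr <- pairs |>
    dplyr::mutate(shade = dplyr::case_when(
      .data$d_prime >= 1 - 1e-9 & .data$lod >= 2 ~ "D' = 1, LOD >= 2",
      .data$d_prime >= 1 - 1e-9 ~ "D' = 1, LOD < 2",
      TRUE ~ "D' < 1"))
  ggplot2::ggplot(pr, ggplot2::aes(x = factor(.data$pos_i),
                                   y = factor(.data$pos_j),
                                   fill = .data$shade)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c("D' = 1, LOD >= 2" = "firebrick",
                                          "D' = 1, LOD < 2" = "steelblue",
                                          "D' < 1" = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
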