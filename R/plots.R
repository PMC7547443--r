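#' Heatmap of an all-against-all similarity matrix
#'
#' @param object an [mcphd_matrix()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mcphd_matrix
#' @export
autoplot.mcphd_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(id1 = rownames(m), id2 = colnames(m))
  df$similarity <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$id2, .data$id1,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tc") +
    ggplot2::theme_minimal()
}

#' Bar chart of a screening table
#'
#' Pair counts per activity category, faceted by threshold.
#'
#' @param object a [screening_table()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot screening_table
#' @export
autoplot.screening_table <- function(object, ...) {
  df <- dplyr::filter(object, !.data$category %in%
                        c("correct", "incorrect", "total"))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$pairs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~threshold) +
    ggplot2::labs(x = NULL, y = "pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Per-atom E-state profile of one molecule
#'
#' @param estates a [sstate3d()] table.
#' @param title optional plot title.
#' @return a ggplot.
#' @export
plot_estate_profile <- function(estates, title = NULL) {
  df <- dplyr::mutate(estates,
                      atom_label = paste0(.data$element, .data$atom))
  df$atom_label <- factor(df$atom_label, levels = df$atom_label)
  ggplot2::ggplot(df, ggplot2::aes(.data$atom_label, .data$sstate3d)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Sstate3D", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
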