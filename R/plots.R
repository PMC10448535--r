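# ggplot2 displays for the result types: enrichment bubble chart, organ
# degree ranking, and an expression/Z-score tile map.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_tile
#'   scale_size_area scale_color_gradient labs theme_minimal
#'   scale_fill_gradient2 scale_fill_viridis_c coord_flip
#' @export
ggplot2::autoplot

#' Bubble chart of an enrichment result
#'
#' Terms against fold change, bubble size the overlap `k`, colour the
#' adjusted p-value (capped at `max_terms` most significant terms).
#'
#' @param object An `organ_enrichment` result.
#' @param max_terms Show at most this many terms (most significant
#'   first). Default 20.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot organ_enrichment
#' @export
autoplot.organ_enrichment <- function(object, max_terms = 20, ...) {
  df <- as_tibble(head(object, max_terms))
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot(df, aes(x = .data$fold, y = .data$term)) +
    geom_point(aes(size = .data$k, color = .data$p_adj)) +
    scale_size_area(max_size = 8) +
    scale_color_gradient(low = "#b2182b", high = "#2166ac") +
    labs(x = "fold enrichment", y = NULL, size = "overlap k",
         color = "adjusted p") +
    theme_minimal()
}

#' Bar chart of an organ degree ranking
#'
#' @param object An `organ_ranking` from [organ_degree_ranking()].
#' @param max_tissues Show at most this many tissues. Default 15.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot organ_ranking
#' @export
autoplot.organ_ranking <- function(object, max_tissues = 15, ...) {
  df <- as_tibble(head(object, max_tissues))
  df$tissue <- factor(df$tissue, levels = rev(df$tissue))
  ggplot(df, aes(x = .data$degree, y = .data$tissue)) +
    geom_col(fill = "#2166ac") +
    labs(x = "linked genes (degree)", y = NULL) +
    theme_minimal()
}

#' Tile map of an expression atlas or Z-score matrix
#'
#' @param object An `expression_atlas` or `zscore_atlas`.
#' @param ... Unused.
#' @return A ggplot; Z-scores use a diverging palette centred at 0,
#'   raw expression a sequential one.
#' @method autoplot expression_atlas
#' @export
autoplot.expression_atlas <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"gene",
                            names_to = "tissue", values_to = "value")
  ggplot(df, aes(x = .data$tissue, y = .data$gene, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "expression") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' @rdname autoplot.expression_atlas
#' @method autoplot zscore_atlas
#' @export
autoplot.zscore_atlas <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"gene",
                            names_to = "tissue", values_to = "z")
  ggplot(df, aes(x = .data$tissue, y = .data$gene, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "Z") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
  }
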