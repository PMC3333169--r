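#' Plot inhibitor production per organism
#'
#' Stacked bars of in-vivo inhibitor counts per organism, split into the
#' part produced by rate-limiting enzymes and the rest.
#'
#' @param production_stats Tibble from [inhibitor_production_stats()].
#' @return A ggplot object.
#' @export
plot_inhibitor_production <- function(production_stats) {
  long <- production_stats |>
    dplyr::transmute(.data$organism,
                     `RLE-produced` = .data$n_rle_produced,
                     Other = .data$n_inhibitors - .data$n_rle_produced) |>
    tidyr::pivot_longer(-"organism", names_to = "source",
                        values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$organism, y = .data$count,
                                     fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("RLE-produced" = "grey15",
                                          Other = "firebrick")) +
    ggplot2::labs(x = NULL, y = "in-vivo inhibitors", fill = NULL,
                  title = "Inhibitor production by rate-limiting enzymes") +
    ggplot2::theme_minimal()
}

#' Plot the cross-pathway inhibition matrix
#'
#' Heat map of the fraction of targets in each pathway category inhibited by
#' rate-limiting providers from each source category, faceted by organism.
#'
#' @param cross_matrix Tibble from [cross_pathway_matrix()].
#' @return A ggplot object.
#' @export
plot_cross_pathway <- function(cross_matrix) {
  ggplot2::ggplot(cross_matrix,
                  ggplot2::aes(x = .data$target_category,
                               y = .data$source_category,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~organism) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "target pathway category", y = "source pathway category",
                  fill = "RLE fraction",
                  title = "Cross-pathway inhibition coverage by rate-limiting providers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot mean profile similarity by pair class
#'
#' Grouped bars of mean Jaccard similarity for the three nested pair
#' classes per organism.
#'
#' @param profile_analysis Result of [profile_similarity_analysis()], or its
#'   `class_means` tibble.
#' @return A ggplot object.
#' @export
plot_class_means <- function(profile_analysis) {
  means <- if (inherits(profile_analysis, "rle_profile_analysis")) {
    profile_analysis$class_means
  } else {
    profile_analysis
  }
  means$pair_class <- factor(means$pair_class,
                             levels = c("common", "rle_provider", "rle_both"))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$organism,
                                      y = .data$mean_jaccard,
                                      fill = .data$pair_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(common = "gold2",
                                          rle_provider = "firebrick",
                                          rle_both = "steelblue")) +
    ggplot2::labs(x = NULL, y = "mean Jaccard similarity", fill = "pair class",
                  title = "Phylogenetic-profile similarity of inhibiting pairs") +
    ggplot2::theme_minimal()
}
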