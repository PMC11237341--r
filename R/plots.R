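#' Plot an RSCU table
#'
#' Classic stacked RSCU bars: one bar per amino-acid family, stacked by
#' codon.
#'
#' @param object A `codon_usage` tibble from [codon_usage()] or [rscu()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot codon_usage
#' @export
autoplot.codon_usage <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$aa, y = .data$rscu,
                               fill = .data$codon_rna)) +
    ggplot2::geom_col(color = "grey20", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::labs(x = "Amino acid", y = "RSCU") +
    ggplot2::theme_minimal()
}

#' Plot per-gene Ka/Ks estimates
#'
#' @param object A `kaks_estimates` tibble from [gene_kaks()].
#' @param ... Unused.
#' @return A ggplot (genes ordered by ratio, dashed line at 1).
#' @method autoplot kaks_estimates
#' @export
autoplot.kaks_estimates <- function(object, ...) {
  df <- dplyr::mutate(object,
                      gene = stats::reorder(.data$gene, -.data$ka_ks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$ka_ks)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Ka/Ks") +
    ggplot2::theme_minimal()
}

#' Plot region composition skews
#'
#' AT skew against GC skew for each region row, the standard view in
#' which PCGs sit in the doubly negative quadrant and the light-strand
#' gene ND6 stands apart with positive GC skew.
#'
#' @param object A `region_composition` tibble from [region_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot region_composition
#' @export
autoplot.region_composition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$at_skew, y = .data$gc_skew)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$region),
                       size = 2.8, vjust = -0.8) +
    ggplot2::labs(x = "AT skew", y = "GC skew") +
    ggplot2::theme_minimal()
}

#' Plot a phylogenetic tree with support values
#'
#' Thin wrapper over `ape::plot.phylo` for trees produced by [nj_tree()]
#' or [bootstrap_tree()].
#'
#' @param tree A `phylo`; node labels (bootstrap percentages) are drawn
#'   when present.
#' @param ... Passed to `ape::plot.phylo`.
#' @return The tree, invisibly.
#' @export
plot_tree <- function(tree, ...) {
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", adj = c(1.2, -0.3),
                    cex = 0.7)
  }
  invisible(tree)
}
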