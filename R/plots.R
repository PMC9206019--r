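#' @importFrom ggplot2 ggplot aes geom_tile geom_boxplot geom_point geom_col
#'   geom_vline facet_wrap labs scale_fill_gradient2 scale_fill_gradientn
#'   theme_minimal autoplot position_jitterdodge
NULL

#' Heatmap of scaled enrichment along pseudotime
#'
#' Gene sets (rows) by window midpoints (columns), one panel per cluster —
#' the virtual-synchronization view of program activity across the cycle.
#'
#' @param es Enrichment tibble from [enrich_virtual_cells()].
#' @param clusters Optional subset of clusters to show.
#' @return A ggplot.
#' @export
plot_enrichment_heatmap <- function(es, clusters = NULL) {
  if (!is.null(clusters)) es <- filter(es, .data$cluster %in% clusters)
  ggplot(es, aes(x = .data$midpoint, y = .data$gene_set,
                 fill = .data$scaled_es)) +
    geom_tile() +
    facet_wrap(~cluster) +
    scale_fill_gradientn(colours = c("#2c7bb6", "#ffffbf", "#d7191c")) +
    labs(x = "pseudotime (window midpoint)", y = NULL,
         fill = "scaled ES") +
    theme_minimal()
}

#' Per-cluster P/Q distribution of gene-set medians
#'
#' Boxes of the median scaled enrichment of every gene set, split by
#' proliferative (P) and quiescent (Q) phase within each cluster.
#'
#' @param medians Medians tibble from [phase_medians()]`$medians`.
#' @return A ggplot.
#' @export
plot_phase_medians <- function(medians) {
  ggplot(medians, aes(x = .data$cluster, y = .data$median_scaled_es,
                      colour = .data$phase)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(position = position_jitterdodge(jitter.width = 0.1),
               size = 0.8, alpha = 0.6) +
    labs(x = "cluster", y = "median scaled ES", colour = "phase") +
    theme_minimal()
}

#' Correlation matrix of (cluster, phase) program profiles
#'
#' @param cor_matrix Correlation matrix from [pattern_classify()].
#' @return A ggplot.
#' @export
plot_pattern_correlation <- function(cor_matrix) {
  df <- as_tibble(cor_matrix, rownames = "from") %>%
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "r")
  ggplot(df, aes(x = .data$from, y = .data$to, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2c7bb6", mid = "white", high = "#d7191c",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' Phase composition per group
#'
#' @param fractions Tibble from [phase_fractions()].
#' @return A ggplot.
#' @export
plot_phase_fractions <- function(fractions) {
  ggplot(fractions, aes(x = .data$group, y = .data$fraction,
                        fill = .data$phase)) +
    geom_col() +
    labs(x = NULL, y = "fraction of cells", fill = "phase") +
    theme_minimal()
}

#' Cell density along pseudotime with band cuts
#'
#' @param cells Tibble with `pt` and `cluster` columns (e.g.
#'   `virtual_sync()$cells`).
#' @param cuts Named band cuts `c(cut_m=, cut_q=)`.
#' @return A ggplot.
#' @export
plot_pseudotime_density <- function(cells, cuts = c(cut_m = 0.20, cut_q = 0.69)) {
  ggplot(cells, aes(x = .data$pt, colour = .data$cluster)) +
    ggplot2::geom_density() +
    geom_vline(xintercept = unname(cuts), linetype = "dashed") +
    labs(x = "pseudotime", y = "density", colour = "cluster") +
    theme_minimal()
}

#' @export
autoplot.virtual_sync <- function(object, type = c("medians", "heatmap",
                                                   "correlation", "density"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
    medians = plot_phase_medians(object$medians),
    heatmap = plot_enrichment_heatmap(object$enrichment),
    correlation = plot_pattern_correlation(object$cor_matrix),
    density = plot_pseudotime_density(object$cells, object$cuts)
  )
}
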