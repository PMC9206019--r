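#' Run the full virtual-synchronization analysis
#'
#' Convenience wrapper chaining the pipeline on a QC-passed count matrix:
#' log-normalization, Louvain clustering, six-set cell-cycle phase scoring,
#' linear pseudotime, band derivation, per-cluster sliding-window virtual
#' cells, ssGSEA enrichment with per-set rescaling, phase medians and
#' pattern classification against the reference cluster.
#'
#' @param counts Sparse cells x genes count matrix (already QC filtered, see
#'   [qc_filter()]).
#' @param cycle_sets Named list of six cell-cycle gene sets (tie-break order
#'   = list order).
#' @param collection Functional gene-set collection for enrichment.
#' @param reference Reference cluster for pattern classification; `NULL`
#'   (default) uses the largest cluster that has windows in both the P and Q
#'   phases (so the reference profiles exist).
#' @param interval,increment Sliding-window geometry (defaults 0.2 / 0.01).
#' @param min_members Minimum cells per virtual cell (default 5).
#' @param resolution Louvain resolution (default 0.2).
#' @param alpha ssGSEA exponent (default 0.75).
#' @param r_threshold Pattern correlation threshold (default 0.3).
#' @param band_method `"bins"` (majority-derived cuts, fixed-cut fallback)
#'   or `"fixed"`.
#' @param seed Seed driving clustering and control-gene draws.
#' @return A `virtual_sync` object: list with `cells` (tibble: `cell_id`,
#'   `cluster`, per-set scores, `phase`, `pt`, `band`), `cuts`, `vc`
#'   (virtual-cell table), `enrichment`, `medians`, `grand_medians`,
#'   `patterns`, `cor_matrix` and `params`.
#' @export
virtual_sync <- function(counts, cycle_sets, collection, reference = NULL,
                         interval = 0.2, increment = 0.01, min_members = 5,
                         resolution = 0.2, alpha = 0.75, r_threshold = 0.3,
                         band_method = c("bins", "fixed"), seed = 1) {
  band_method <- match.arg(band_method)
  norm <- log_normalize(counts)
  clusters <- cluster_cells(norm, resolution = resolution, seed = seed)
  scores <- score_cell_cycle(norm, cycle_sets, seed = seed)
  pt <- infer_linear_pseudotime(norm, cycle_sets, phases = scores$phase)
  bands <- derive_bands(pt, scores$phase, method = band_method)
  cuts <- attr(bands, "cuts")

  cells <- scores %>%
    left_join(clusters, by = "cell_id") %>%
    left_join(select(bands, "cell_id", "pt", "band"), by = "cell_id")

  vc <- virtual_cells(norm, cells, make_windows(interval, increment),
                      min_members = min_members)
  es <- enrich_virtual_cells(vc, collection, alpha = alpha)
  med <- phase_medians(es, cuts)
  if (is.null(reference)) {
    # the reference must span both phases: take the largest (first-lettered)
    # cluster with P and Q medians
    has_both <- med$medians %>%
      distinct(.data$cluster, .data$phase) %>%
      count(.data$cluster) %>%
      filter(.data$n == 2) %>%
      pull(.data$cluster)
    if (length(has_both) == 0) {
      abort("no cluster has windows in both P and Q phases")
    }
    reference <- sort(has_both)[1]
  }
  pat <- pattern_classify(med$medians, reference = reference,
                          r_threshold = r_threshold)

  structure(list(
    cells = cells, cuts = cuts, vc = vc, enrichment = es,
    medians = med$medians, grand_medians = med$grand,
    patterns = pat$labels, cor_matrix = pat$cor_matrix,
    params = list(interval = interval, increment = increment,
                  min_members = min_members, resolution = resolution,
                  alpha = alpha, r_threshold = r_threshold,
                  reference = reference, band_method = band_method,
                  seed = seed)
  ), class = "virtual_sync")
}

#' @export
print.virtual_sync <- function(x, ...) {
  cat("virtual_sync analysis\n")
  cat(sprintf("  %d cells in %d clusters; band cuts M|P = %.3f, P|Q = %.3f\n",
              nrow(x$cells), length(unique(x$cells$cluster)),
              x$cuts[["cut_m"]], x$cuts[["cut_q"]]))
  cat(sprintf("  %d virtual cells, %d gene sets enriched\n",
              ncol(x$vc$expr), length(unique(x$enrichment$gene_set))))
  pats <- x$patterns[x$patterns$cluster != x$params$reference, ]
  cat(sprintf("  patterns vs cluster %s: %s\n", x$params$reference,
              paste(sprintf("%s.%s=%s", pats$cluster, pats$phase, pats$pattern),
                    collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-(cluster, phase) pattern summary
#'
#' @param x A `virtual_sync` object.
#' @param ... Unused.
#' @return Tibble: one row per (cluster, phase) with grand median, reference
#'   correlations and pattern label.
#' @export
tidy.virtual_sync <- function(x, ...) {
  x$patterns %>%
    left_join(mutate(x$grand_medians, phase = as.character(.data$phase)),
              by = c("cluster", "phase")) %>%
    arrange(.data$cluster, .data$phase)
}

#' One-row pipeline summary
#'
#' @param x A `virtual_sync` object.
#' @param ... Unused.
#' @export
glance.virtual_sync <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n_clusters = length(unique(x$cells$cluster)),
    n_virtual_cells = ncol(x$vc$expr),
    n_gene_sets = length(unique(x$enrichment$gene_set)),
    cut_m = x$cuts[["cut_m"]],
    cut_q = x$cuts[["cut_q"]],
    frac_q = mean(x$cells$band == "Q"),
    reference = x$params$reference
  )
}
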