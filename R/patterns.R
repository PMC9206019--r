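#' Median scaled enrichment per (cluster, phase)
#'
#' Collapses the per-window scaled enrichment scores to one median per gene
#' set, cluster and phase, where the phase of a window is the band of its
#' midpoint and mitosis-band (`M`) windows fold into the proliferative phase
#' `P` (the P band is everything below the quiescence cut). Also returns the
#' grand median across gene sets per (cluster, phase) — the summary points of
#' a cluster's overall program activity.
#'
#' @param es Enrichment tibble from [enrich_virtual_cells()] (needs
#'   `gene_set`, `cluster`, `midpoint`, `scaled_es`).
#' @param cuts Band cuts, see [assign_window_band()].
#' @return List with `medians` (tibble: `gene_set`, `cluster`, `phase`,
#'   `median_scaled_es`, `n_windows`) and `grand` (tibble: `cluster`,
#'   `phase`, `grand_median`).
#' @export
phase_medians <- function(es, cuts = c(cut_m = 0.20, cut_q = 0.69)) {
  stopifnot(all(c("gene_set", "cluster", "midpoint", "scaled_es") %in% names(es)))
  banded <- es %>%
    mutate(
      band = assign_window_band(.data$midpoint, cuts),
      phase = factor(ifelse(.data$band == "Q", "Q", "P"), levels = c("P", "Q"))
    )
  medians <- banded %>%
    group_by(.data$gene_set, .data$cluster, .data$phase) %>%
    summarise(median_scaled_es = median(.data$scaled_es),
              n_windows = dplyr::n_distinct(.data$vc_id), .groups = "drop")

  missing_q <- setdiff(unique(medians$cluster),
                       unique(medians$cluster[medians$phase == "Q"]))
  if (length(missing_q) > 0) {
    inform(paste0("clusters without Q-phase windows: ",
                  paste(missing_q, collapse = ", ")))
  }
  grand <- medians %>%
    group_by(.data$cluster, .data$phase) %>%
    summarise(grand_median = median(.data$median_scaled_es), .groups = "drop")
  list(medians = medians, grand = grand)
}

#' Classify cluster phases into P-like / Q-like / anti-P patterns
#'
#' Each (cluster, phase) vector of per-gene-set medians is correlated with
#' the reference cluster's P and Q vectors. A (cluster, phase) is `P-like`
#' when its correlation with reference-P is the larger of the two and at
#' least `r_threshold`, `Q-like` when the reference-Q correlation is the
#' larger and at least `r_threshold`, `anti-P` when the reference-P
#' correlation is at most `-r_threshold`, and `unclassified` otherwise.
#'
#' @param medians Medians tibble from [phase_medians()]`$medians`.
#' @param reference Reference cluster label (default `"A"`, the largest
#'   cluster).
#' @param r_threshold Correlation magnitude separating a pattern from
#'   `unclassified` (default 0.3).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return List with `labels` (tibble: `cluster`, `phase`, `cor_ref_p`,
#'   `cor_ref_q`, `pattern`) and `cor_matrix` (symmetric correlation matrix
#'   over all (cluster, phase) median vectors).
#' @export
pattern_classify <- function(medians, reference = "A", r_threshold = 0.3,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- medians %>%
    mutate(key = paste0(.data$cluster, ".", .data$phase)) %>%
    select("gene_set", "key", "median_scaled_es") %>%
    tidyr::pivot_wider(names_from = "key", values_from = "median_scaled_es")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$gene_set
  if (nrow(mat) < 3) abort("need at least 3 gene sets to correlate patterns")

  ref_p <- paste0(reference, ".P")
  ref_q <- paste0(reference, ".Q")
  if (!ref_p %in% colnames(mat) || !ref_q %in% colnames(mat)) {
    abort(paste0("reference cluster '", reference,
                 "' lacks P or Q phase medians"))
  }
  cor_matrix <- suppressWarnings(
    cor(mat, use = "pairwise.complete.obs", method = method))

  labels <- purrr::map_dfr(colnames(mat), function(key) {
    rp <- cor_matrix[key, ref_p]
    rq <- cor_matrix[key, ref_q]
    pattern <- if (is.na(rp) || is.na(rq)) {
      "unclassified"
    } else if (rp <= -r_threshold) {
      "anti-P"
    } else if (rp >= rq && rp >= r_threshold) {
      "P-like"
    } else if (rq > rp && rq >= r_threshold) {
      "Q-like"
    } else {
      "unclassified"
    }
    tibble(cluster = sub("\\.[PQ]$", "", key),
           phase = sub("^.*\\.", "", key),
           cor_ref_p = rp, cor_ref_q = rq, pattern = pattern)
  })
  list(labels = labels, cor_matrix = cor_matrix,
       reference = reference, r_threshold = r_threshold)
}
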