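#' Single-sample GSEA enrichment score
#'
#' Rank-based running-sum enrichment of one gene set in one expression
#' profile. Genes are ordered by decreasing profile value (ties broken by
#' gene name, so the walk is deterministic across platforms); walking down
#' the list, the in-set cumulative weight `P_in` and the uniform out-of-set
#' cumulative `P_out` are accumulated and the score is the sum of their
#' differences over all positions:
#' `ES = sum_i (P_in(i) - P_out(i))`.
#' With `weight = "rank"` (the default) the in-set increment at position `i`
#' is `|r_i|^alpha` where `r_i` is the rank-normalized value (`N` for the top
#' gene down to 1, average ranks on ties); with `weight = "value"` the raw
#' profile value is used.
#'
#' @param profile Named numeric vector (one expression profile).
#' @param gene_set Character vector of gene names.
#' @param alpha Weighting exponent (default 0.75); `alpha = 0` gives the
#'   rank-only statistic, invariant to any strictly monotone transform of
#'   the profile.
#' @param weight `"rank"` or `"value"` in-set weighting.
#' @return A single numeric enrichment score.
#' @export
ssgsea <- function(profile, gene_set, alpha = 0.75,
                   weight = c("rank", "value")) {
  weight <- match.arg(weight)
  if (is.null(names(profile))) abort("profile must be named by gene")
  n <- length(profile)
  if (n < 2) abort("profile must cover at least 2 genes")
  in_set <- names(profile) %in% gene_set
  m <- sum(in_set)
  if (m == 0) abort("gene set shares no genes with the profile")
  if (m == n) abort("gene set covers the whole profile; enrichment undefined")

  ord <- order(-profile, names(profile))
  in_set <- in_set[ord]
  w <- if (weight == "rank") {
    # rank-normalized value: N for the largest, averaged on ties
    rank(profile, ties.method = "average")[ord]
  } else {
    profile[ord]
  }
  w <- abs(w)^alpha

  p_in <- cumsum(ifelse(in_set, w, 0))
  denom_in <- p_in[n]
  if (denom_in == 0) abort("all in-set weights are zero")
  p_in <- p_in / denom_in
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' Score virtual cells against a gene-set collection
#'
#' Runs [ssgsea()] for every (virtual cell, gene set) pair and min-max
#' rescales the scores per gene set with [scale_scores()]. Collection genes
#' absent from the virtual-cell profiles are dropped per set (counted in the
#' `dropped_per_set` attribute); sets left empty, or covering every profiled
#' gene, are skipped with a warning.
#'
#' @param vc A `virtual_cell_table` from [virtual_cells()].
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha,weight Passed to [ssgsea()].
#' @return Tibble `(gene_set, vc_id, cluster, window, midpoint, es,
#'   scaled_es)`.
#' @export
enrich_virtual_cells <- function(vc, collection, alpha = 0.75,
                                 weight = c("rank", "value")) {
  weight <- match.arg(weight)
  stopifnot(inherits(vc, "virtual_cell_table"))
  genes <- rownames(vc$expr)
  usable <- list()
  dropped <- integer(0)
  for (nm in names(collection)) {
    found <- intersect(collection[[nm]], genes)
    dropped[nm] <- length(collection[[nm]]) - length(found)
    if (length(found) == 0 || length(found) == length(genes)) {
      warn(paste0("skipping gene set '", nm,
                  "': no usable genes in the virtual-cell profiles"))
      next
    }
    usable[[nm]] <- found
  }
  if (length(usable) == 0) abort("no gene set overlaps the profiled genes")

  es <- purrr::map_dfr(seq_len(ncol(vc$expr)), function(j) {
    profile <- vc$expr[, j]
    names(profile) <- genes
    tibble(
      gene_set = names(usable),
      vc_id = colnames(vc$expr)[j],
      es = vapply(usable, function(gs) ssgsea(profile, gs, alpha, weight),
                  numeric(1))
    )
  })
  es <- left_join(es, select(vc$windows, "vc_id", "cluster", "window", "midpoint"),
                  by = "vc_id")
  out <- scale_scores(es)
  attr(out, "alpha") <- alpha
  attr(out, "dropped_per_set") <- dropped
  out
}

#' Min-max rescale enrichment scores per gene set
#'
#' For each gene set, `scaled_es = (es - min) / (max - min)` over ALL
#' (cluster, window) entries, so every gene set spans exactly `[0, 1]` unless
#' it is constant, in which case all its scaled values are 0.5 (with a
#' warning). Rescaling is affine-invariant and order-preserving.
#'
#' @param es Data frame with `gene_set` and `es` columns.
#' @return The input with a `scaled_es` column added (replaced if present).
#' @export
scale_scores <- function(es) {
  stopifnot(all(c("gene_set", "es") %in% names(es)))
  out <- es %>%
    group_by(.data$gene_set) %>%
    mutate(scaled_es = minmax01(.data$es)) %>%
    ungroup()
  if (anyNA(out$scaled_es)) {
    warn("constant gene set(s): scaled enrichment set to 0.5")
    out$scaled_es[is.na(out$scaled_es)] <- 0.5
  }
  out
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(NA_real_, length(x)))
  (x - r[1]) / (r[2] - r[1])
}
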