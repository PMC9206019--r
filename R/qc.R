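#' Quality-control filtering of cells and genes
#'
#' Cell metrics (detected genes, mitochondrial fraction) are computed on the
#' ORIGINAL gene universe; cells failing any cell rule are removed first, then
#' genes expressed in fewer than `min_cells_per_gene` of the surviving cells
#' are removed. Boundary cells are kept: removal requires strictly fewer than
#' `min_genes` detected, strictly more than `max_genes`, or a mitochondrial
#' fraction strictly above `max_mito_frac`.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param min_cells_per_gene Keep genes detected in at least this many
#'   surviving cells (default 3).
#' @param min_genes,max_genes Keep cells with detected-gene count in
#'   `[min_genes, max_genes]` (defaults 200 and 3700).
#' @param max_mito_frac Keep cells whose mitochondrial transcript fraction is
#'   at most this (default 0.10).
#' @param mito_pattern Regular expression identifying mitochondrial genes by
#'   symbol (default `"^MT-"`).
#' @return The filtered count matrix, with a `qc_report` attribute (tibble of
#'   cells/genes removed per rule).
#' @export
qc_filter <- function(counts, min_cells_per_gene = 3, min_genes = 200,
                      max_genes = 3700, max_mito_frac = 0.10,
                      mito_pattern = "^MT-") {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito <- grepl(mito_pattern, colnames(counts))
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::rowSums(counts[, mito, drop = FALSE])) / pmax(total, 1)
  } else {
    rep(0, nrow(counts))
  }

  low <- detected < min_genes
  high <- detected > max_genes
  mt <- mito_frac > max_mito_frac
  keep_cell <- !(low | high | mt)
  if (!any(keep_cell)) abort("no cells survive QC (empty after QC)")

  kept <- counts[keep_cell, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(kept > 0)
  keep_gene <- cells_per_gene >= min_cells_per_gene
  out <- kept[, keep_gene, drop = FALSE]

  attr(out, "qc_report") <- tibble(
    rule = c("cells_low_genes", "cells_high_genes", "cells_high_mito",
             "genes_low_cells"),
    removed = c(sum(low), sum(high & !low), sum(mt & !low & !high),
                sum(!keep_gene))
  )
  out
}

#' Depth-normalize and log-transform counts
#'
#' Per cell: `log(1 + count / total_counts * scale_factor)`. Zero counts map
#' to exactly zero and the result is invariant to per-cell depth scaling.
#'
#' @param counts Sparse cells x genes count matrix (QC-passed).
#' @param scale_factor Target depth (default `1e4`).
#' @return Sparse cells x genes matrix of log-normalized expression.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  total <- Matrix::rowSums(counts)
  if (any(total == 0)) abort("cells with zero total counts cannot be normalized")
  norm <- methods::as(counts, "CsparseMatrix")
  # dgCMatrix stores row indices of nonzeros in @i (0-based)
  row_of_x <- norm@i + 1L
  norm@x <- log1p(norm@x / total[row_of_x] * scale_factor)
  norm
}

#' Per-gene standardized (scaled) expression
#'
#' Centers and scales each gene across cells, clipping at `clip` to bound the
#' leverage of extreme cells; constant genes scale to zero.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param clip Symmetric clip bound (default 10).
#' @return Dense cells x genes matrix.
#' @export
scale_genes <- function(norm, clip = 10) {
  x <- as.matrix(norm)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  pmin(pmax(z, -clip), clip)
}
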