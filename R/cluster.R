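#' Graph-based Louvain clustering of cells
#'
#' Selects highly variable genes by a variance-stabilizing ranking (observed
#' variance over the loess-expected variance at each gene's mean), runs PCA on
#' the scaled variable genes, builds a k-nearest-neighbour graph on the top
#' principal components, and partitions it with Louvain community detection.
#' Cluster labels are letters assigned by decreasing cluster size (`A` =
#' largest; ties broken by smallest contained cell index), so labels are
#' canonical across runs.
#'
#' @param norm Cells x genes log-normalized matrix (see [log_normalize()]).
#' @param n_var_genes Number of variable genes to keep (default 2000).
#' @param n_pcs Principal components for the neighbour graph (default 50).
#' @param k_neighbors Neighbours per cell (default 20).
#' @param resolution Louvain resolution (default 0.2).
#' @param seed Integer seed for the community detection.
#' @return Tibble `(cell_id, cluster)` with the parameters used and the PCA
#'   embedding attached as attributes `params` and `embedding`.
#' @export
cluster_cells <- function(norm, n_var_genes = 2000, n_pcs = 50,
                          k_neighbors = 20, resolution = 0.2, seed = 1) {
  n <- nrow(norm)
  if (n < k_neighbors + 1) {
    abort(sprintf("need at least %d cells for k = %d neighbours",
                  k_neighbors + 1, k_neighbors))
  }
  hv <- variable_genes(norm, n_var_genes)
  z <- scale_genes(norm[, hv, drop = FALSE])
  if (all(abs(z) < 1e-12)) {
    # no expression variation at all: a single community by definition
    out <- tibble(cell_id = rownames(norm), cluster = "A")
    attr(out, "params") <- list(n_var_genes = length(hv), n_pcs = 0,
                                k_neighbors = k_neighbors,
                                resolution = resolution, seed = seed)
    return(out)
  }
  n_pcs <- min(n_pcs, ncol(z) - 1L, n - 1L)
  pcs <- prcomp(z, rank. = n_pcs, center = FALSE, scale. = FALSE)$x

  nn <- knn_indices(pcs, k_neighbors)
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)

  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)

  # canonical letters: A = largest community, size ties by smallest cell index
  sizes <- table(memb)
  first_idx <- vapply(names(sizes), function(k) min(which(memb == k)), 1L)
  ord <- order(-as.integer(sizes), first_idx)
  relabel <- setNames(make_cluster_letters(length(sizes)), names(sizes)[ord])
  labels <- unname(relabel[as.character(memb)])

  out <- tibble(cell_id = rownames(norm), cluster = labels)
  attr(out, "params") <- list(n_var_genes = length(hv), n_pcs = n_pcs,
                              k_neighbors = k_neighbors,
                              resolution = resolution, seed = seed)
  attr(out, "embedding") <- pcs
  out
}

make_cluster_letters <- function(k) {
  if (k <= 26) LETTERS[seq_len(k)] else {
    c(LETTERS, paste0("Z", seq_len(k - 26)))[seq_len(k)]
  }
}

#' Rank genes by standardized variance
#'
#' Fits `log10(variance) ~ log10(mean)` by loess over expressed genes and
#' ranks genes by observed/expected variance; returns the top `n` gene names.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param n Number of genes to return.
#' @return Character vector of gene names.
#' @export
variable_genes <- function(norm, n = 2000) {
  x <- norm
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(x) / max(nrow(x) - 1, 1)
  ok <- mu > 0 & v > 0
  if (sum(ok) <= n) return(colnames(x)[order(-v)][seq_len(min(n, ncol(x)))])
  fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3, degree = 2)
  std_var <- rep(-Inf, ncol(x))
  std_var[ok] <- log10(v[ok]) - predict(fit)
  colnames(x)[order(-std_var)][seq_len(n)]
}

# brute-force k nearest neighbours in PC space; fine for the cell counts
# this pipeline targets (thousands), avoids an ANN dependency
knn_indices <- function(x, k) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  diag(d2) <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}
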