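#' Linear cell-cycle pseudotime
#'
#' Orders cells along a one-dimensional trajectory from mitosis to quiescence
#' using only cycle-gene expression: (1) cells are compared by Spearman
#' correlation of their cycle-gene profiles (distance `1 - rho`); (2) the
#' distance matrix is embedded in `n_dims` dimensions by classical
#' multidimensional scaling; (3) an initial path is drawn through `k_centers`
#' k-means centroids ordered by the shortest Hamiltonian path; (4) the path is
#' refined by principal-curve iterations (project cells onto the path, smooth
#' each embedding coordinate against arc-length position, repeat) until the
#' mean projection change falls below `tol`; (5) arc-length positions are
#' rescaled to `[0, 1]` and oriented so mitotic cells sit at low pseudotime.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param cycle_sets Named list of cycle gene sets; their union defines the
#'   trajectory genes.
#' @param n_dims Embedding dimensions (default 3).
#' @param k_centers Centroids for the initial path (default 4).
#' @param phases Optional per-cell phase labels (vector aligned with the
#'   matrix rows, or named by cell). When given, the axis is flipped so that
#'   `mean(pt | G2M or M) < mean(pt | G0)`; otherwise the mean expression of
#'   the first cycle set (assumed mitotic) anchors the low end.
#' @param span Smoother span for the principal-curve refinement, as a
#'   fraction of points (default 0.2).
#' @param max_iter,tol Refinement cap and convergence tolerance on the mean
#'   absolute change in pseudotime (defaults 50 and 1e-4).
#' @return Tibble `(cell_id, pt)` with `pt` in `[0, 1]`; attributes
#'   `orientation_flipped`, `n_dims`, `iterations`.
#' @export
infer_linear_pseudotime <- function(norm, cycle_sets, n_dims = 3,
                                    k_centers = 4, phases = NULL,
                                    span = 0.2, max_iter = 50, tol = 1e-4) {
  genes <- intersect(unique(unlist(cycle_sets, use.names = FALSE)),
                     colnames(norm))
  if (length(genes) < 3) abort("too few cycle genes found in the matrix")
  n <- nrow(norm)
  if (n < 10) abort("at least 10 cells are required")
  if (n < k_centers) abort("fewer cells than path centroids")
  # canonical cell order: pseudotime is then exactly invariant to the row
  # order of the input matrix
  input_ids <- rownames(norm)
  canon <- order(input_ids)
  x <- as.matrix(norm[canon, genes, drop = FALSE])

  # Spearman distance between cells
  rk <- t(apply(x, 1, rank))
  cc <- suppressWarnings(cor(t(rk)))
  cc[is.na(cc)] <- 1
  d <- pmax(1 - cc, 0)
  if (max(d) < 1e-12) abort("constant expression: all pairwise distances are zero")

  emb <- cmdscale(stats::as.dist(d), k = n_dims)
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = 1)
  # canonical signs: the largest-magnitude cell on each axis points positive,
  # so the embedding (and everything downstream) is cell-order invariant
  for (j in seq_len(ncol(emb))) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }

  ids <- input_ids[canon]
  # deterministic k-means: centers seeded at quantile positions of coord 1
  ord1 <- order(emb[, 1], ids)
  qpos <- ord1[pmax(1L, round((2 * seq_len(k_centers) - 1) / (2 * k_centers) * n))]
  centers0 <- emb[qpos, , drop = FALSE]
  centers0 <- centers0 + outer(seq_len(k_centers) * 1e-9, rep(1, ncol(emb)))
  km <- suppressWarnings(kmeans(emb, centers = centers0, iter.max = 100))
  cent <- km$centers

  path <- cent[hamiltonian_order(cent), , drop = FALSE]
  lambda <- project_polyline(emb, path)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    path <- smooth_path(emb, lambda, span = span)
    lambda_new <- project_polyline(emb, path)
    delta <- mean(abs(lambda_new - lambda))
    lambda <- lambda_new
    if (delta < tol) break
  }

  pt <- rescale01(lambda)
  if (!is.null(phases) && is.null(names(phases))) {
    phases <- setNames(as.character(phases), input_ids)
  }
  flipped <- orient_pt(pt, x, cycle_sets, phases, ids)
  if (flipped) pt <- 1 - pt

  out <- tibble(cell_id = input_ids,
                pt = pt[match(input_ids, ids)])
  attr(out, "orientation_flipped") <- flipped
  attr(out, "n_dims") <- ncol(emb)
  attr(out, "iterations") <- iterations
  out
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

orient_pt <- function(pt, norm, cycle_sets, phases, cell_ids) {
  if (!is.null(phases)) {
    ph <- if (!is.null(names(phases))) as.character(phases[cell_ids]) else as.character(phases)
    mito <- ph %in% c("G2M", "M")
    g0 <- ph %in% "G0"
    if (any(mito) && any(g0)) {
      return(mean(pt[mito]) > mean(pt[g0]))
    }
  }
  # anchor: the first cycle set is taken as the mitosis-entry program
  anchor_genes <- intersect(cycle_sets[[1]], colnames(norm))
  anchor <- Matrix::rowMeans(norm[, anchor_genes, drop = FALSE])
  cor(pt, as.numeric(anchor)) > 0
}

# shortest Hamiltonian path over a handful of centroids, by enumeration
hamiltonian_order <- function(centers) {
  k <- nrow(centers)
  d <- as.matrix(stats::dist(centers))
  perms <- permutations_of(seq_len(k))
  best <- NULL
  best_len <- Inf
  for (p in perms) {
    len <- sum(d[cbind(p[-k], p[-1])])
    if (len < best_len - 1e-12) {
      best_len <- len
      best <- p
    }
  }
  best
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# arc-length position (normalized to [0,1]) of each point's nearest
# projection onto the polyline with vertex matrix `path`
project_polyline <- function(pts, path) {
  m <- nrow(path)
  if (m < 2) return(rep(0, nrow(pts)))
  seg_vec <- path[-1, , drop = FALSE] - path[-m, , drop = FALSE]
  seg_len <- sqrt(rowSums(seg_vec^2))
  keep <- seg_len > 1e-12
  cum <- c(0, cumsum(seg_len))
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_arc <- rep(0, n)
  for (j in which(keep)) {
    a <- path[j, ]
    v <- seg_vec[j, ]
    tj <- (sweep(pts, 2, a) %*% v) / (seg_len[j]^2)
    tj <- pmin(pmax(as.numeric(tj), 0), 1)
    proj <- outer(tj, v) + matrix(a, n, length(a), byrow = TRUE)
    d2 <- rowSums((pts - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[j] + tj[upd] * seg_len[j]
  }
  total <- cum[m]
  if (total < 1e-12) rep(0, n) else best_arc / total
}

# refit the curve: smooth every embedding coordinate against the current
# arc-length order and resample 100 vertices along it
smooth_path <- function(emb, lambda, span = 0.2, n_vertices = 100) {
  grid <- seq(min(lambda), max(lambda), length.out = n_vertices)
  vert <- vapply(seq_len(ncol(emb)), function(j) {
    sm <- lowess(lambda, emb[, j], f = span)
    approx(sm$x, sm$y, xout = grid, rule = 2, ties = mean)$y
  }, numeric(n_vertices))
  matrix(vert, nrow = n_vertices)
}

#' Derive mitosis / proliferation / quiescence bands from bin majorities
#'
#' Cuts pseudotime into fixed-width bins and labels each bin by the phase
#' super-group holding more than half of its cells: mitosis (`G2M`, `M`),
#' growth (`MG1`, `G1S`, `S`) or quiescence (`G0`); bins with no majority are
#' `mixed`. When the non-empty bin labels form a clean mitosis -> growth ->
#' quiescence progression, the band cuts are placed at the changepoints (the
#' left edge of the first growth-majority bin and of the first
#' quiescence-majority bin); otherwise the fixed cuts `fallback_cuts` are
#' used with a warning. Cells are then banded as `M` (`pt < cut_m`), `P`
#' (`cut_m <= pt < cut_q`) or `Q` (`pt >= cut_q`).
#'
#' @param pt Tibble from [infer_linear_pseudotime()], or a numeric vector
#'   named by cell.
#' @param phases Per-cell phase labels aligned with `pt`.
#' @param bin_width Bin width on the pseudotime axis (default 0.05).
#' @param method `"bins"` derives the cuts from bin majorities with fallback;
#'   `"fixed"` always uses `fallback_cuts`.
#' @param min_bin_cells Bins with fewer cells are treated as empty when
#'   deriving cuts (default 10): a majority over a handful of cells is not a
#'   usable estimate.
#' @param fallback_cuts `c(cut_m, cut_q)`, default `c(0.20, 0.69)`.
#' @return Tibble `(cell_id, pt, band)` with attribute `cuts` (named numeric
#'   `cut_m`, `cut_q`) and `cuts_derived` (logical).
#' @export
derive_bands <- function(pt, phases, bin_width = 0.05,
                         method = c("bins", "fixed"), min_bin_cells = 10,
                         fallback_cuts = c(0.20, 0.69)) {
  method <- match.arg(method)
  if (is.data.frame(pt)) {
    cell_id <- pt$cell_id
    ptv <- pt$pt
  } else {
    cell_id <- names(pt) %||% as.character(seq_along(pt))
    ptv <- as.numeric(pt)
  }
  stopifnot(length(phases) == length(ptv))
  super <- super_group(as.character(phases))

  cuts <- c(cut_m = fallback_cuts[1], cut_q = fallback_cuts[2])
  derived <- FALSE
  if (method == "bins") {
    bc <- bin_majority_cuts(ptv, super, bin_width, min_bin_cells)
    if (is.null(bc)) {
      warn("no clean mitosis -> growth -> quiescence changepoints in bin majorities; falling back to fixed cuts")
    } else {
      cuts <- bc
      derived <- TRUE
    }
  }

  band <- ifelse(ptv < cuts[["cut_m"]], "M",
                 ifelse(ptv < cuts[["cut_q"]], "P", "Q"))
  out <- tibble(cell_id = cell_id, pt = ptv,
                band = factor(band, levels = c("M", "P", "Q")))
  attr(out, "cuts") <- cuts
  attr(out, "cuts_derived") <- derived
  out
}

super_group <- function(phase) {
  dplyr::case_when(
    phase %in% c("G2M", "M") ~ "M",
    phase %in% c("MG1", "G1S", "S") ~ "P",
    phase %in% "G0" ~ "Q",
    TRUE ~ NA_character_
  )
}

bin_majority_cuts <- function(pt, super, bin_width, min_bin_cells = 1) {
  n_bins <- ceiling(1 / bin_width)
  bin <- pmin(floor(pt / bin_width) + 1L, n_bins)
  lab <- vapply(seq_len(n_bins), function(b) {
    g <- super[bin == b]
    g <- g[!is.na(g)]
    if (length(g) < max(min_bin_cells, 1)) return(NA_character_)
    fr <- table(g) / length(g)
    top <- names(fr)[which.max(fr)]
    if (fr[[top]] > 0.5) top else "mixed"
  }, character(1))

  occupied <- which(!is.na(lab) & lab != "mixed")
  m_bins <- occupied[lab[occupied] == "M"]
  p_bins <- occupied[lab[occupied] == "P"]
  q_bins <- occupied[lab[occupied] == "Q"]
  if (length(m_bins) == 0 || length(p_bins) == 0 || length(q_bins) == 0) return(NULL)
  if (max(m_bins) > min(p_bins) || max(p_bins) > min(q_bins)) return(NULL)
  c(cut_m = (min(p_bins) - 1) * bin_width,
    cut_q = (min(q_bins) - 1) * bin_width)
}
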