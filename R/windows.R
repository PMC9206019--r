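#' Sliding pseudotime windows
#'
#' Overlapping windows `[s, s + interval]` with `s = 0, increment,
#' 2*increment, ..., 1 - interval` (inclusive, tolerance 1e-9) over the
#' pseudotime range `[0, 1]`. A cell belongs to a window when
#' `start <= pt < end`; the final window additionally includes `pt = 1`.
#' The defaults give 81 windows, the first `[0, 0.20]` and the last
#' `[0.80, 1.00]`, with every interior pseudotime covered by exactly
#' `interval / increment = 20` windows.
#'
#' @param interval Window width as a fraction of the range (default 0.2).
#' @param increment Step between window starts (default 0.01).
#' @return Tibble `(window, start, end, midpoint)`.
#' @export
make_windows <- function(interval = 0.2, increment = 0.01) {
  if (!(interval > 0 && interval <= 1)) abort("interval must be in (0, 1]")
  if (!(increment > 0 && increment <= interval)) {
    abort("increment must be in (0, interval]")
  }
  n_steps <- floor((1 - interval) / increment + 1e-9)
  starts <- seq(0L, n_steps) * increment
  tibble(
    window = seq_along(starts),
    start = starts,
    end = starts + interval,
    midpoint = starts + interval / 2
  )
}

#' Cells belonging to one window
#'
#' @param pt Numeric pseudotime vector.
#' @param start,end Window bounds.
#' @param is_last Whether this is the final window (then `pt = 1` is
#'   included).
#' @param tol Floating-point comparison tolerance.
#' @return Logical vector.
#' @export
window_members <- function(pt, start, end, is_last = FALSE, tol = 1e-9) {
  inside <- pt >= start - tol & pt < end - tol
  if (is_last) inside | abs(pt - end) <= tol else inside
}

#' Aggregate cells into per-(cluster, window) virtual cells
#'
#' For every cluster and sliding window, member cells are summarized into one
#' "virtual cell" in three stages. Stage 1 takes the shifted geometric mean
#' of each gene's depth-normalized expression over the member cells:
#' `g = exp(mean(log(1 + expr))) - 1`, where `expr` is the normalized matrix
#' mapped back to the linear scale (`expm1`), so a plain geometric mean is
#' not annihilated by zeros. Stage 2 divides by the per-gene median of `g`
#' pooled over ALL (cluster, window) virtual cells; genes whose pooled median
#' is zero are dropped (logged in the `dropped_genes` attribute). Stage 3
#' log-transforms: `v = log2(1 + g / median)`.
#'
#' Windows are laid over the GLOBAL pseudotime range for every cluster, so
#' virtual cells from different clusters share one axis; windows with fewer
#' than `min_members` member cells are dropped, not errors.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param cells Data frame with `cell_id`, `pt` and `cluster` columns (e.g.
#'   a join of the pseudotime and clustering tables).
#' @param windows Window table from [make_windows()].
#' @param min_members Minimum cells per virtual cell (default 5).
#' @return A `virtual_cell_table`: list with `expr` (genes x virtual cells
#'   stage-3 matrix), `windows` (tibble: `vc_id`, `cluster`, `window`,
#'   `start`, `end`, `midpoint`, `n_cells`), and attributes
#'   `dropped_genes`, `dropped_windows`.
#' @export
virtual_cells <- function(norm, cells, windows = make_windows(),
                          min_members = 5) {
  stopifnot(all(c("cell_id", "pt", "cluster") %in% names(cells)))
  cells <- cells[match(rownames(norm), cells$cell_id), ]
  if (anyNA(cells$cell_id)) abort("cells table must cover every row of the matrix")

  is_last <- windows$end >= max(windows$end) - 1e-9
  clusters <- sort(unique(cells$cluster))

  meta <- list()
  stage1 <- list()
  for (cl in clusters) {
    in_cl <- which(cells$cluster == cl)
    for (w in seq_len(nrow(windows))) {
      members <- in_cl[window_members(cells$pt[in_cl], windows$start[w],
                                      windows$end[w], is_last[w])]
      if (length(members) < min_members) next
      vc_id <- sprintf("%s_w%03d", cl, windows$window[w])
      # shifted geometric mean on the linear scale: log1p(expm1(norm)) = norm,
      # so stage 1 reduces to expm1 of the member mean of normalized values
      stage1[[vc_id]] <- expm1(Matrix::colMeans(norm[members, , drop = FALSE]))
      meta[[vc_id]] <- tibble(
        vc_id = vc_id, cluster = cl, window = windows$window[w],
        start = windows$start[w], end = windows$end[w],
        midpoint = windows$midpoint[w], n_cells = length(members)
      )
    }
  }
  if (length(stage1) == 0) abort("no window reached min_members cells")

  g <- do.call(cbind, stage1)  # genes x virtual cells
  med <- apply(g, 1, median)
  keep <- med > 0
  v <- log2(1 + g[keep, , drop = FALSE] / med[keep])

  out <- list(expr = v, windows = bind_rows(meta), stage1 = g)
  attr(out, "dropped_genes") <- rownames(g)[!keep]
  n_possible <- length(clusters) * nrow(windows)
  attr(out, "dropped_windows") <- n_possible - ncol(g)
  class(out) <- "virtual_cell_table"
  out
}

#' @export
print.virtual_cell_table <- function(x, ...) {
  cat(sprintf(
    "virtual_cell_table: %d genes x %d virtual cells (%d clusters; %d zero-median genes dropped)\n",
    nrow(x$expr), ncol(x$expr), length(unique(x$windows$cluster)),
    length(attr(x, "dropped_genes"))
  ))
  invisible(x)
}

#' Band of a window midpoint
#'
#' Maps window midpoints onto the M / P / Q bands using the band cuts:
#' `M` if `midpoint < cut_m`, `P` if `cut_m <= midpoint < cut_q`, `Q` if
#' `midpoint >= cut_q`.
#'
#' @param midpoint Numeric midpoints.
#' @param cuts Named numeric `c(cut_m=, cut_q=)`, e.g. the `cuts` attribute
#'   of [derive_bands()]; defaults to the fixed cuts 0.20 / 0.69.
#' @return Factor in levels `M`, `P`, `Q`.
#' @export
assign_window_band <- function(midpoint, cuts = c(cut_m = 0.20, cut_q = 0.69)) {
  band <- ifelse(midpoint < cuts[["cut_m"]], "M",
                 ifelse(midpoint < cuts[["cut_q"]], "P", "Q"))
  factor(band, levels = c("M", "P", "Q"))
}

#' Long tidy view of a virtual-cell table
#'
#' @param x A `virtual_cell_table`.
#' @param ... Unused.
#' @return Tibble `(gene, vc_id, cluster, midpoint, value)`.
#' @export
tidy.virtual_cell_table <- function(x, ...) {
  expr <- as_tibble(x$expr, rownames = "gene")
  long <- tidyr::pivot_longer(expr, -"gene", names_to = "vc_id",
                              values_to = "value")
  left_join(long, select(x$windows, "vc_id", "cluster", "midpoint"),
            by = "vc_id")
}
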