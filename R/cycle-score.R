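#' Expression-bin-matched module score
#'
#' Scores each cell for a gene set as the mean expression of the set genes
#' minus the mean expression of control genes matched on average expression:
#' genes are ranked by mean expression across cells and cut into `n_bins`
#' equal-frequency bins; for every set gene, `n_ctrl` control genes are drawn
#' (with replacement) from its bin. Set genes absent from the matrix are
#' ignored, so the score is invariant to padding a set with unmeasured genes.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param gene_set Character vector of gene symbols.
#' @param n_bins Expression bins for control matching (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @param set_name Optional set name; used in error messages and to give each
#'   set its own control-draw RNG stream (seed + name hash).
#' @return Numeric vector of per-cell scores, named by cell.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1, set_name = NULL) {
  present <- intersect(gene_set, colnames(norm))
  if (length(present) == 0) {
    abort(paste0("no genes of set '", set_name %||% "(unnamed)",
                 "' are present in the matrix"))
  }
  n_bins <- min(n_bins, ncol(norm))
  gene_means <- Matrix::colMeans(norm)
  # equal-frequency bins on the mean-expression ranking
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk / length(rk) * n_bins)
  names(bin) <- colnames(norm)

  draw_seed <- if (is.null(set_name)) seed else (seed + str_hash(set_name)) %% 2147483647L
  ctrl <- with_seed(draw_seed, {
    unlist(lapply(present, function(g) {
      # controls come from the same expression bin, excluding the set itself
      pool <- setdiff(colnames(norm)[bin == bin[[g]]], present)
      if (length(pool) == 0) pool <- colnames(norm)[bin == bin[[g]]]
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }), use.names = FALSE)
  })

  set_mean <- Matrix::rowMeans(norm[, present, drop = FALSE])
  # controls keep multiplicity: the draw defines the weighting
  tab <- table(ctrl)
  ctrl_mean <- as.numeric(norm[, names(tab), drop = FALSE] %*% as.numeric(tab)) / length(ctrl)
  setNames(as.numeric(set_mean - ctrl_mean), rownames(norm))
}

#' Score cells against a cycle gene-set collection and assign phases
#'
#' Runs [module_score()] for every set in the collection and assigns each
#' cell the phase whose set scores highest (ties broken by the collection's
#' set order, first wins). Every cell receives a phase even when all scores
#' are negative.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param cycle_sets Named list of gene sets, e.g. from [read_gmt()]; the
#'   set order fixes the tie-break priority.
#' @inheritParams module_score
#' @return Tibble with `cell_id`, one score column per set, and `phase`.
#' @export
score_cell_cycle <- function(norm, cycle_sets, n_bins = 24, n_ctrl = 100,
                             seed = 1) {
  stopifnot(length(cycle_sets) >= 1, !is.null(names(cycle_sets)))
  scores <- purrr::map(names(cycle_sets), function(nm) {
    module_score(norm, cycle_sets[[nm]], n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = seed, set_name = nm)
  })
  names(scores) <- names(cycle_sets)
  tbl <- as_tibble(scores)
  tbl <- mutate(tbl, cell_id = rownames(norm), .before = 1)
  mutate(tbl, phase = assign_phase(tbl, names(cycle_sets)))
}

#' Assign each cell the max-scoring phase
#'
#' @param scores Data frame with one numeric column per phase set.
#' @param phase_order Character vector naming the score columns in tie-break
#'   priority order (first wins on exact ties).
#' @return Factor of phase labels with levels `phase_order`.
#' @export
assign_phase <- function(scores, phase_order) {
  m <- as.matrix(scores[, phase_order, drop = FALSE])
  if (anyNA(m)) abort("phase scores contain missing values")
  idx <- apply(m, 1, which.max)  # which.max returns the FIRST maximum
  factor(phase_order[idx], levels = phase_order)
}

#' Phase composition per group
#'
#' @param meta Data frame with one row per cell.
#' @param phase,group Column names (strings) holding the per-cell phase and
#'   the grouping label.
#' @return Tibble `(group, phase, n, fraction, label)`; fractions sum to 1
#'   within each group and `label` is the report-ready percent rendering from
#'   [percent_label()].
#' @export
phase_fractions <- function(meta, phase = "phase", group = "sample") {
  meta %>%
    count(group = .data[[group]], phase = .data[[phase]], name = "n") %>%
    group_by(.data$group) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(label = percent_label(.data$fraction))
}

#' Percent label with magnitude-dependent precision
#'
#' Renders a proportion the way the study reports contingency fractions: one
#' decimal place below 10%, whole percent at or above 10%, truncating (not
#' rounding) at the displayed precision — e.g. 230/7814 -> `"2.9%"` and
#' 133/230 -> `"57%"`.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Character vector of labels.
#' @export
percent_label <- function(p) {
  pct <- p * 100
  vapply(pct, function(x) {
    # epsilon guards exact percentages against binary representation error
    if (x < 10) sprintf("%.1f%%", trunc(x * 10 + 1e-9) / 10)
    else sprintf("%d%%", as.integer(trunc(x + 1e-9)))
  }, character(1))
}
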