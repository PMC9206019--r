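# Independent oracles and small fixtures used across the suite.

# Literal position-by-position ssGSEA walk, kept deliberately loop-based and
# separate from the package's vectorized implementation.
oracle_ssgsea <- function(profile, gene_set, alpha = 0.75) {
  nms <- names(profile)
  ord <- order(-profile, nms)
  in_set <- nms[ord] %in% gene_set
  n <- length(profile)
  m <- sum(in_set)
  rk <- rank(profile, ties.method = "average")[ord]
  denom <- sum(abs(rk[in_set])^alpha)
  es <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_in <- p_in + abs(rk[i])^alpha / denom
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Brute-force shifted geometric mean per gene over a dense member matrix
# (cells x genes of linear-scale expression).
oracle_geomean <- function(expr) {
  apply(expr, 2, function(col) prod(1 + col)^(1 / length(col)) - 1)
}

# Small dense log-normalized matrix with named cells/genes.
random_norm_matrix <- function(n_cells, n_genes, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n_cells * n_genes), n_cells, n_genes)
    m[sample(length(m), length(m) %/% 3)] <- 0
    dimnames(m) <- list(paste0("cell", seq_len(n_cells)),
                        paste0("g", seq_len(n_genes)))
    Matrix::Matrix(log1p(m), sparse = TRUE)
  })
}

# Compact simulation config for fast module tests: full 603-gene cycle
# programs, but trimmed functional/noise gene load.
small_sim_config <- function(n_cells = 300, quiescent_fraction = 0.3,
                             seed = 1, ...) {
  sim_config(
    samples = data.frame(sample = "s1", n_cells = n_cells,
                         quiescent_fraction = quiescent_fraction),
    n_program_genes = 20, n_noise_genes = 100, seed = seed, ...
  )
}

# Noise-free cells on a 1-D trajectory: genes are Gaussian bumps whose peaks
# tile the axis, so distances grow smoothly with separation in t.
gradient_matrix <- function(n_cells = 60, n_genes = 40, t = NULL) {
  t <- t %||% seq(0, 1, length.out = n_cells)
  peaks <- seq(0, 1, length.out = n_genes)
  m <- vapply(peaks, function(p) exp(-(t - p)^2 / (2 * 0.15^2)),
              numeric(length(t)))
  dimnames(m) <- list(paste0("cell", seq_along(t)),
                      paste0("g", seq_len(n_genes)))
  list(norm = Matrix::Matrix(m, sparse = TRUE), t = t,
       sets = list(early = paste0("g", 1:10),
                   mid = paste0("g", 11:30),
                   late = paste0("g", 31:40)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
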