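PHASES <- c("G2M", "M", "MG1", "G1S", "S", "G0")

# peak pseudotime of each phase program on the linear mitosis -> quiescence
# axis: mitosis band < 0.2, growth band [0.2, 0.69), quiescence >= 0.69
PHASE_PEAKS <- c(G2M = 0.05, M = 0.15, MG1 = 0.28, G1S = 0.445, S = 0.61, G0 = 0.845)
PHASE_STARTS <- c(G2M = 0, M = 0.1, MG1 = 0.2, G1S = 0.3633, S = 0.5267, G0 = 0.69)

#' Simulation configuration
#'
#' Builds the parameter set for [simulate_counts()]. The defaults emulate the
#' study conditions the pipeline was designed for: several isogenic samples
#' dominated by cycling cells with a quiescent (G0) subpopulation of tunable
#' prevalence, 603 cycle genes split across six phase programs, and
#' sample/phase-specific functional programs layered on top.
#'
#' @param samples Data frame with columns `sample`, `n_cells` and
#'   `quiescent_fraction` (in `[0,1]`). Defaults to three samples with G0
#'   fractions 0.21, 0.61 and 0.30 (untreated, early-resistant,
#'   late-resistant conditions).
#' @param n_cycle_genes Total cycle genes split across the six phase sets
#'   (default 603, split 100/100/100/100/100/103).
#' @param n_program_genes Genes per functional program set (default 40).
#' @param program_activity Data frame `(program, sample, band, multiplier)`
#'   giving the fold change applied to a program's genes for cells of that
#'   sample in that pseudotime band (`M`, `P` or `Q`); missing combinations
#'   default to 1. `NULL` uses [default_program_activity()].
#' @param n_noise_genes Unstructured background genes (default 600).
#' @param n_mito_genes Mitochondrial (`MT-` prefixed) genes (default 10),
#'   tuned so the expected mitochondrial fraction is ~5%.
#' @param library_size Mean total counts per cell (default 5000).
#' @param libsize_sdlog Log-normal spread of per-cell library size (default 0.15).
#' @param dispersion Negative-binomial size parameter shared by all genes
#'   (default 2); `Inf` gives Poisson sampling.
#' @param dropout Extra zero-inflation probability in `[0,1]` (default 0).
#' @param cycle_amplitude Peak fold elevation of a cycle gene over its
#'   baseline at its phase peak (default 5; strong, clearly learnable programs).
#' @param bump_sd Width (sd of the Gaussian bump, pseudotime units) of each
#'   phase program (default 0.10).
#' @param quiescence_cut Pseudotime at which quiescence begins (default 0.69).
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(samples = NULL,
                       n_cycle_genes = 603,
                       n_program_genes = 40,
                       program_activity = NULL,
                       n_noise_genes = 600,
                       n_mito_genes = 10,
                       library_size = 5000,
                       libsize_sdlog = 0.15,
                       dispersion = 2,
                       dropout = 0,
                       cycle_amplitude = 5,
                       bump_sd = 0.10,
                       quiescence_cut = 0.69,
                       seed = 1) {
  if (is.null(samples)) {
    samples <- tibble(
      sample = c("untreated", "resist_early", "resist_late"),
      n_cells = c(500L, 500L, 500L),
      quiescent_fraction = c(0.21, 0.61, 0.30)
    )
  }
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) abort("at least one sample is required")
  stopifnot(all(c("sample", "n_cells", "quiescent_fraction") %in% names(samples)))
  if (any(samples$quiescent_fraction < 0 | samples$quiescent_fraction > 1)) {
    abort("quiescent_fraction must be in [0, 1]")
  }
  if (any(samples$n_cells < 1)) abort("each sample needs at least one cell")
  if (!is.finite(library_size) || library_size <= 0) {
    abort("library_size must be positive")
  }
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (dropout < 0 || dropout > 1) abort("dropout must be in [0, 1]")
  if (is.null(program_activity)) {
    program_activity <- default_program_activity(samples$sample)
  }
  program_activity <- as_tibble(program_activity)
  if (nrow(program_activity) > 0 && any(program_activity$multiplier < 0)) {
    abort("program multipliers must be >= 0")
  }

  structure(list(
    samples = samples, n_cycle_genes = n_cycle_genes,
    n_program_genes = n_program_genes, program_activity = program_activity,
    n_noise_genes = n_noise_genes, n_mito_genes = n_mito_genes,
    library_size = library_size, libsize_sdlog = libsize_sdlog,
    dispersion = dispersion, dropout = dropout,
    cycle_amplitude = cycle_amplitude, bump_sd = bump_sd,
    quiescence_cut = quiescence_cut, seed = seed
  ), class = "sim_config")
}

#' Default functional-program activity map
#'
#' Ten hallmark-like programs: checkpoint/growth programs active in
#' proliferation and shut down in quiescence, quiescence programs induced in
#' the Q band, one state program per sample (so samples separate into
#' clusters), and a flat housekeeping program.
#'
#' @param sample_names Character vector of sample labels.
#' @return Tibble `(program, sample, band, multiplier)`.
#' @export
default_program_activity <- function(sample_names) {
  bands <- c("M", "P", "Q")
  grid <- tidyr::expand_grid(sample = sample_names, band = bands)

  cycle_dep <- bind_rows(
    mutate(grid, program = "CHECKPOINT_A",
           multiplier = ifelse(.data$band == "Q", 0.4, 3)),
    mutate(grid, program = "CHECKPOINT_B",
           multiplier = ifelse(.data$band == "Q", 0.4, 3)),
    mutate(grid, program = "GROWTH_MTOR",
           multiplier = ifelse(.data$band == "Q", 0.5, 2.5)),
    mutate(grid, program = "QUIESCENCE_HH",
           multiplier = ifelse(.data$band == "Q", 3, 0.6)),
    mutate(grid, program = "QUIESCENCE_IFN",
           multiplier = ifelse(.data$band == "Q", 2.5, 0.6)),
    mutate(grid, program = "HOUSEKEEPING", multiplier = 1)
  )

  state <- purrr::imap_dfr(sample_names, function(sm, i) {
    mutate(grid, program = paste0("STATE_", toupper(sm)),
           multiplier = ifelse(.data$sample == sm, 3, 0.4))
  })
  # one flat stress program shared by all, mildly quiescence-leaning
  stress <- mutate(grid, program = "STRESS_RESPONSE",
                   multiplier = ifelse(.data$band == "Q", 1.5, 1))

  select(bind_rows(cycle_dep, state, stress),
         "program", "sample", "band", "multiplier")
}

#' Simulate cell-cycle structured UMI counts with ground truth
#'
#' Places each cell on a linear pseudotime from mitosis (0) to deep
#' quiescence (1): cycling cells uniform on `[0, quiescence_cut)`, quiescent
#' cells uniform on `[quiescence_cut, 1]`. Cycle genes follow smooth Gaussian
#' bump programs peaked at phase-specific positions; functional-program genes
#' are multiplicatively modulated per (sample, band); counts are drawn from a
#' negative binomial with the configured library size and dispersion,
#' optionally thinned by Bernoulli dropout.
#'
#' @param config A [sim_config()].
#' @param return_means If `TRUE`, attach the cells x genes expected-mean
#'   matrix as `$mu` (dense; only for small simulations).
#' @return A `sim_data` list: `counts` (sparse cells x genes), `truth`
#'   (tibble: `cell_id`, `sample`, `true_cluster`, `true_pseudotime`,
#'   `true_phase`), `cycle_sets` and `program_sets` (GMT-ready lists), and
#'   `gene_info`.
#' @export
simulate_counts <- function(config = sim_config(), return_means = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_counts_impl(config, return_means))
}

simulate_counts_impl <- function(cfg, return_means) {
  smp <- cfg$samples
  n_cells <- sum(smp$n_cells)

  ## --- ground truth: pseudotime, phase, sample ---
  sample_of <- rep(smp$sample, smp$n_cells)
  qf <- rep(smp$quiescent_fraction, smp$n_cells)
  is_g0 <- runif(n_cells) < qf
  qc <- cfg$quiescence_cut
  pt <- ifelse(is_g0, runif(n_cells, qc, 1), runif(n_cells, 0, qc))
  phase <- phase_from_pt(pt, qc)
  band <- band_from_pt(pt, qc)
  cell_id <- sprintf("%s_c%05d", sample_of, stats::ave(
    seq_len(n_cells), sample_of, FUN = seq_along))

  ## --- gene universe ---
  set_sizes <- c(rep(cfg$n_cycle_genes %/% 6, 5),
                 cfg$n_cycle_genes - 5 * (cfg$n_cycle_genes %/% 6))
  cycle_sets <- purrr::map2(PHASES, set_sizes, function(ph, k) {
    sprintf("CYC_%s_%03d", ph, seq_len(k))
  })
  names(cycle_sets) <- PHASES

  prog_names <- unique(cfg$program_activity$program)
  program_sets <- lapply(prog_names, function(p) {
    sprintf("%s_%03d", p, seq_len(cfg$n_program_genes))
  })
  names(program_sets) <- prog_names

  noise_genes <- if (cfg$n_noise_genes > 0) sprintf("NOISE_%04d", seq_len(cfg$n_noise_genes)) else character(0)
  mito_genes <- if (cfg$n_mito_genes > 0) sprintf("MT-G%d", seq_len(cfg$n_mito_genes)) else character(0)

  genes <- c(unlist(cycle_sets, use.names = FALSE),
             unlist(program_sets, use.names = FALSE),
             noise_genes, mito_genes)
  n_genes <- length(genes)
  gene_type <- rep(c("cycle", "program", "noise", "mito"),
                   c(sum(set_sizes), length(prog_names) * cfg$n_program_genes,
                     length(noise_genes), length(mito_genes)))
  gene_set <- rep(c(PHASES, prog_names, "none", "none"),
                  c(set_sizes, rep(cfg$n_program_genes, length(prog_names)),
                    length(noise_genes), length(mito_genes)))

  base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  # pin mitochondrial content at ~5% of the expected transcriptome
  if (length(mito_genes) > 0) {
    mito_idx <- gene_type == "mito"
    base[mito_idx] <- base[mito_idx] *
      (0.05 / 0.95) * sum(base[!mito_idx]) / sum(base[mito_idx])
  }

  ## --- expected relative expression, cells x genes ---
  w <- matrix(rep(base, each = n_cells), nrow = n_cells, ncol = n_genes,
              dimnames = list(cell_id, genes))
  for (ph in PHASES) {
    bump <- 1 + cfg$cycle_amplitude *
      exp(-(pt - PHASE_PEAKS[[ph]])^2 / (2 * cfg$bump_sd^2))
    idx <- which(gene_set == ph & gene_type == "cycle")
    w[, idx] <- w[, idx] * bump
  }
  if (length(prog_names) > 0) {
    act <- cfg$program_activity
    for (p in prog_names) {
      mult <- rep(1, n_cells)
      pa <- act[act$program == p, ]
      for (r in seq_len(nrow(pa))) {
        hit <- sample_of == pa$sample[r] & band == pa$band[r]
        mult[hit] <- pa$multiplier[r]
      }
      idx <- which(gene_set == p)
      w[, idx] <- w[, idx] * mult
    }
  }

  rel <- w / Matrix::rowSums(w)
  libsize <- cfg$library_size * rlnorm(n_cells, -cfg$libsize_sdlog^2 / 2,
                                       cfg$libsize_sdlog)
  mu <- rel * libsize

  ## --- observation model ---
  counts <- if (is.infinite(cfg$dispersion)) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = cfg$dispersion)
  }
  if (cfg$dropout > 0) {
    counts <- counts * rbinom(length(counts), 1, 1 - cfg$dropout)
  }
  cm <- matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
  counts_sp <- methods::as(Matrix::Matrix(cm, sparse = TRUE), "CsparseMatrix")

  out <- list(
    counts = counts_sp,
    truth = tibble(
      cell_id = cell_id, sample = sample_of, true_cluster = sample_of,
      true_pseudotime = pt, true_phase = phase, true_band = band
    ),
    cycle_sets = cycle_sets,
    program_sets = program_sets,
    gene_info = tibble(gene = genes, type = gene_type, set = gene_set,
                       base_mean = base),
    config = cfg
  )
  if (return_means) out$mu <- mu
  structure(out, class = "sim_data")
}

phase_from_pt <- function(pt, quiescence_cut = 0.69) {
  starts <- PHASE_STARTS
  starts[["G0"]] <- quiescence_cut
  idx <- findInterval(pt, starts)
  factor(PHASES[idx], levels = PHASES)
}

band_from_pt <- function(pt, quiescence_cut = 0.69, mitosis_cut = 0.2) {
  ifelse(pt < mitosis_cut, "M", ifelse(pt < quiescence_cut, "P", "Q"))
}
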