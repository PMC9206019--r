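test_that("same seed gives identical simulations", {
  cfg <- small_sim_config(n_cells = 80, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
})

test_that("cycle sets partition the 603 cycle genes", {
  sim <- simulate_counts(small_sim_config(n_cells = 30))
  genes <- unlist(sim$cycle_sets, use.names = FALSE)
  expect_length(genes, 603)
  expect_false(anyDuplicated(genes) > 0)
  expect_equal(unname(sort(lengths(sim$cycle_sets))),
               c(100, 100, 100, 100, 100, 103))
})

test_that("simulated G0 fraction matches the configured prevalence", {
  cfg <- sim_config(samples = data.frame(sample = "s", n_cells = 2000,
                                         quiescent_fraction = 0.61),
                    seed = 3)
  sim <- simulate_counts(cfg)
  phat <- mean(sim$truth$true_phase == "G0")
  ci <- 2.576 * sqrt(0.61 * 0.39 / 2000)  # binomial 99% CI half-width
  expect_lt(abs(phat - 0.61), ci)
  # quiescent cells sit beyond the quiescence cut, cycling cells before it
  g0 <- sim$truth$true_phase == "G0"
  expect_true(all(sim$truth$true_pseudotime[g0] >= 0.69))
  expect_true(all(sim$truth$true_pseudotime[!g0] < 0.69))
})

test_that("noise-free limit recovers the specified means", {
  cfg <- sim_config(samples = data.frame(sample = "s", n_cells = 400,
                                         quiescent_fraction = 0.3),
                    n_program_genes = 10, n_noise_genes = 50,
                    library_size = 1e5, libsize_sdlog = 0,
                    dispersion = Inf, dropout = 0, seed = 5)
  sim <- simulate_counts(cfg, return_means = TRUE)
  obs <- Matrix::colMeans(sim$counts)
  exp_mean <- colMeans(sim$mu)
  hi <- exp_mean >= 20
  expect_gt(sum(hi), 100)
  expect_lt(max(abs(obs[hi] - exp_mean[hi]) / exp_mean[hi]), 0.05)
})

test_that("cycle-program peaks follow the mitosis-to-quiescence order", {
  cfg <- small_sim_config(n_cells = 400, quiescent_fraction = 0.4, seed = 2)
  sim <- simulate_counts(cfg, return_means = TRUE)
  rel <- sim$mu / rowSums(sim$mu)
  peak_pt <- vapply(sim$cycle_sets, function(gs) {
    set_mean <- rowMeans(rel[, gs])
    sim$truth$true_pseudotime[which.max(set_mean)]
  }, numeric(1))
  expect_true(all(diff(peak_pt[c("G2M", "M", "MG1", "G1S", "S", "G0")]) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(samples = data.frame(sample = "s", n_cells = 10,
                                               quiescent_fraction = 1.2)),
               "quiescent_fraction")
  expect_error(sim_config(library_size = 0), "library_size")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(samples = data.frame(sample = character(0),
                                               n_cells = integer(0),
                                               quiescent_fraction = numeric(0))),
               "sample")
})

test_that("fixtures round-trip through the reader", {
  sim <- simulate_counts(small_sim_config(n_cells = 40, seed = 9))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_counts(dir)
  expect_equal(as.matrix(back), as.matrix(sim$counts))
  expect_identical(rownames(back), rownames(sim$counts))
  expect_identical(colnames(back), colnames(sim$counts))
  sets <- read_gmt(file.path(dir, "cycle_sets.gmt"))
  expect_identical(sets$G2M, sim$cycle_sets$G2M)
})

test_that("a three-sample fixture lists three sample labels", {
  cfg <- sim_config(samples = data.frame(
    sample = c("a", "b", "c"), n_cells = c(20, 20, 20),
    quiescent_fraction = c(0.1, 0.5, 0.9)),
    n_program_genes = 5, n_noise_genes = 20, seed = 4)
  sim <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(unique(truth$sample), c("a", "b", "c"))
})

test_that("an empty matrix round-trips as zero cells", {
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(0, 3),
                            dimnames = list(character(0), c("g1", "g2", "g3")))
  dir <- withr::local_tempdir()
  write_fixture(m, dir)
  back <- read_counts(dir)
  expect_equal(nrow(back), 0)
  expect_equal(ncol(back), 3)
})
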