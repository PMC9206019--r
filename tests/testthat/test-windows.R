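test_that("default windows enumerate to 81 with the stated bounds", {
  w <- make_windows(0.2, 0.01)
  expect_equal(nrow(w), 81)
  expect_equal(c(w$start[1], w$end[1]), c(0, 0.20))
  expect_equal(c(w$start[81], w$end[81]), c(0.80, 1.00))
  expect_equal(w$midpoint, w$start + 0.1)
})

test_that("degenerate window geometries behave", {
  w1 <- make_windows(1, 0.5)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 1))
  w2 <- make_windows(0.5, 0.5)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$start, c(0, 0.5))
  expect_error(make_windows(0, 0.01), "interval")
  expect_error(make_windows(0.2, 0.3), "increment")
})

test_that("every covered pseudotime falls in exactly interval/increment windows", {
  w <- make_windows(0.2, 0.01)
  is_last <- seq_len(nrow(w)) == nrow(w)
  count_windows <- function(pt) {
    sum(vapply(seq_len(nrow(w)), function(i) {
      window_members(pt, w$start[i], w$end[i], is_last[i])
    }, logical(1)))
  }
  grid <- seq(0.2, 0.8, by = 0.01)
  expect_true(all(vapply(grid, count_windows, numeric(1)) == 20))
  rand <- withr::with_seed(1, runif(50, 0.2, 0.8))
  expect_true(all(vapply(rand, count_windows, numeric(1)) == 20))
  # edges: pt = 1 only in the final window, pt = 0 only in windows starting at 0
  expect_equal(count_windows(1), 1)
  expect_equal(count_windows(0), 1)
})

make_vc_input <- function(n_cells, n_genes, seed = 1) {
  withr::with_seed(seed, {
    expr <- matrix(rexp(n_cells * n_genes), n_cells, n_genes,
                   dimnames = list(paste0("c", seq_len(n_cells)),
                                   paste0("g", seq_len(n_genes))))
    expr[sample(length(expr), length(expr) %/% 4)] <- 0
    norm <- Matrix::Matrix(log1p(expr), sparse = TRUE)
    cells <- tibble::tibble(cell_id = rownames(expr),
                            pt = runif(n_cells),
                            cluster = sample(c("A", "B"), n_cells, TRUE))
    list(expr = expr, norm = norm, cells = cells)
  })
}

test_that("stage-1 aggregation equals the brute-force geometric mean", {
  d <- make_vc_input(40, 15, seed = 2)
  vc <- virtual_cells(d$norm, d$cells, make_windows(0.5, 0.25),
                      min_members = 1)
  is_last <- c(FALSE, FALSE, TRUE)
  w <- make_windows(0.5, 0.25)
  for (j in seq_len(ncol(vc$stage1))) {
    info <- vc$windows[j, ]
    members <- d$cells$cluster == info$cluster &
      window_members(d$cells$pt, info$start, info$end,
                     is_last[info$window])
    expected <- oracle_geomean(d$expr[members, , drop = FALSE])
    expect_equal(unname(vc$stage1[, j]), unname(expected), tolerance = 1e-10)
  }
})

test_that("geometric-mean hand cases hold", {
  # three members with linear expression (0, 1, 3) -> (1*2*4)^(1/3) - 1 = 1
  norm <- Matrix::Matrix(log1p(matrix(c(0, 1, 3), 3, 1,
                                      dimnames = list(paste0("c", 1:3), "g"))),
                         sparse = TRUE)
  cells <- tibble::tibble(cell_id = paste0("c", 1:3), pt = c(0.1, 0.1, 0.1),
                          cluster = "A")
  vc <- virtual_cells(norm, cells, make_windows(1, 1), min_members = 1)
  expect_equal(unname(vc$stage1[1, 1]), 1, tolerance = 1e-12)
  # constant members: the geometric mean is the constant
  norm2 <- Matrix::Matrix(log1p(matrix(2.5, 4, 1,
                                       dimnames = list(paste0("c", 1:4), "g"))),
                          sparse = TRUE)
  cells2 <- tibble::tibble(cell_id = paste0("c", 1:4), pt = 0.5, cluster = "A")
  vc2 <- virtual_cells(norm2, cells2, make_windows(1, 1), min_members = 1)
  expect_equal(unname(vc2$stage1[1, 1]), 2.5, tolerance = 1e-12)
  # a single member passes through unchanged
  vc3 <- virtual_cells(norm[1:1, , drop = FALSE],
                       cells[1, ], make_windows(1, 1), min_members = 1)
  expect_equal(unname(vc3$stage1[1, 1]), 0, tolerance = 1e-12)
})

test_that("stage-2 normalization gives per-gene median exactly one", {
  d <- make_vc_input(60, 12, seed = 5)
  vc <- virtual_cells(d$norm, d$cells, make_windows(0.2, 0.1), min_members = 1)
  med <- apply(vc$stage1, 1, median)
  r <- vc$stage1[med > 0, , drop = FALSE] / med[med > 0]
  expect_equal(unname(apply(r, 1, median)), rep(1, sum(med > 0)))
  # stage 3 is log2(1 + r) of the kept genes
  expect_equal(vc$expr, log2(1 + r))
})

test_that("underpopulated windows are dropped, not errors", {
  d <- make_vc_input(200, 8, seed = 7)
  vc <- virtual_cells(d$norm, d$cells, make_windows(0.2, 0.2), min_members = 10)
  expect_true(all(vc$windows$n_cells >= 10))
  cells_one <- d$cells
  cells_one$pt <- 0.05  # everything in the first window
  expect_error(virtual_cells(d$norm, cells_one, make_windows(0.1, 0.1),
                             min_members = 500), "min_members")
})

test_that("window midpoints map onto bands at the stated boundaries", {
  expect_equal(as.character(assign_window_band(c(0.10, 0.40, 0.80))),
               c("M", "P", "Q"))
  expect_equal(as.character(assign_window_band(0.69)), "Q")
  expect_equal(as.character(assign_window_band(0.199999)), "M")
})
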