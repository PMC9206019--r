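make_medians <- function(ref_p, clusters) {
  sets <- paste0("hall", seq_along(ref_p))
  ref_q <- rev(ref_p) * 0.5 + 0.25
  rows <- list(
    tibble::tibble(gene_set = sets, cluster = "A", phase = "P",
                   median_scaled_es = ref_p),
    tibble::tibble(gene_set = sets, cluster = "A", phase = "Q",
                   median_scaled_es = ref_q)
  )
  for (nm in names(clusters)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_set = sets, cluster = nm, phase = "P",
      median_scaled_es = clusters[[nm]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_set = sets, cluster = nm, phase = "Q",
      median_scaled_es = clusters[[nm]])
  }
  dplyr::bind_rows(rows)
}

ref_p <- seq(0.05, 0.95, length.out = 12)

test_that("an identical cluster is P-like with correlation exactly 1", {
  med <- make_medians(ref_p, list(Y = ref_p))
  pat <- pattern_classify(med, reference = "A")
  y <- pat$labels[pat$labels$cluster == "Y" & pat$labels$phase == "P", ]
  expect_identical(y$pattern, "P-like")
  expect_equal(y$cor_ref_p, 1.0)
})

test_that("inverting the reference program yields anti-P in both phases", {
  med <- make_medians(ref_p, list(X = 1 - ref_p))
  pat <- pattern_classify(med, reference = "A")
  x <- pat$labels[pat$labels$cluster == "X", ]
  expect_equal(x$pattern, c("anti-P", "anti-P"))
  expect_true(all(x$cor_ref_p < -0.9))
})

test_that("the reference's own phases classify as expected", {
  med <- make_medians(ref_p, list())
  pat <- pattern_classify(med, reference = "A")
  a_p <- pat$labels[pat$labels$cluster == "A" & pat$labels$phase == "P", ]
  expect_identical(a_p$pattern, "P-like")
  expect_equal(a_p$cor_ref_p, 1.0)
  expect_true(isSymmetric(pat$cor_matrix))
  expect_equal(unname(diag(pat$cor_matrix)), rep(1, ncol(pat$cor_matrix)))
})

test_that("weakly correlated profiles are unclassified", {
  # orthogonal-ish vector: alternating around the reference mean
  wig <- rep(c(0.45, 0.55), 6)
  med <- make_medians(ref_p, list(W = wig))
  pat <- pattern_classify(med, reference = "A", r_threshold = 0.3)
  expect_true(all(pat$labels$pattern[pat$labels$cluster == "W"] == "unclassified"))
})

test_that("labels are invariant to gene-set order and need 3+ sets", {
  med <- make_medians(ref_p, list(X = 1 - ref_p, Y = ref_p))
  shuffled <- withr::with_seed(1, med[sample(nrow(med)), ])
  a <- pattern_classify(med)$labels
  b <- pattern_classify(shuffled)$labels
  expect_equal(dplyr::arrange(a, cluster, phase),
               dplyr::arrange(b, cluster, phase))
  expect_error(pattern_classify(make_medians(ref_p[1:2], list())), "3 gene sets")
})

test_that("phase medians collapse windows with M folded into P", {
  es <- tibble::tibble(
    gene_set = "s1",
    vc_id = paste0("A_w", 1:5),
    cluster = "A",
    midpoint = c(0.1, 0.3, 0.5, 0.8, 0.9),   # M, P, P, Q, Q
    scaled_es = c(0.3, 0.3, 0.3, 0.9, 0.7)
  )
  pm <- phase_medians(es)
  p_med <- pm$medians$median_scaled_es[pm$medians$phase == "P"]
  q_med <- pm$medians$median_scaled_es[pm$medians$phase == "Q"]
  expect_equal(p_med, 0.3)  # constant P windows (M window folds in)
  expect_equal(q_med, 0.8)
  # odd count (0, 0.5, 1) -> 0.5
  es2 <- tibble::tibble(gene_set = "s", vc_id = paste0("B_w", 1:3),
                        cluster = "B", midpoint = c(0.3, 0.4, 0.5),
                        scaled_es = c(0, 0.5, 1))
  expect_equal(phase_medians(es2)$medians$median_scaled_es, 0.5)
})

test_that("quiescence-boosted programs show higher Q than P medians", {
  withr::with_seed(11, {
    mids <- make_windows()$midpoint
    boosted <- tibble::tibble(
      gene_set = "boosted", vc_id = paste0("A_w", seq_along(mids)),
      cluster = "A", midpoint = mids,
      es = ifelse(mids >= 0.69, 2, 1) + rnorm(length(mids), sd = 0.1)
    )
  })
  pm <- phase_medians(scale_scores(boosted))$medians
  expect_gt(pm$median_scaled_es[pm$phase == "Q"],
            pm$median_scaled_es[pm$phase == "P"])
})

test_that("clusters without Q windows are flagged, not fatal", {
  es <- tibble::tibble(
    gene_set = rep(paste0("s", 1:3), each = 2),
    vc_id = rep(c("C_w1", "C_w2"), 3),
    cluster = "C", midpoint = rep(c(0.3, 0.4), 3),
    scaled_es = runif(6)
  )
  expect_message(pm <- phase_medians(es), "without Q")
  expect_true(all(pm$medians$phase == "P"))
})
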