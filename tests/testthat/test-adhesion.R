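half_coated_assay <- function(n = 100, on_coated = 0, h = 60, w = 60) {
  mask <- matrix(FALSE, h, w)
  mask[, seq_len(w / 2)] <- TRUE     # left half coated -> f_area = 0.5
  x_on <- runif(n * on_coated, 0, w / 2 - 1)
  x_off <- runif(n * (1 - on_coated), w / 2, w - 1)
  cells <- cell_records(id = seq_len(n), x = c(x_on, x_off),
                        y = runif(n, 0, h - 1), area = 10, cell_type = "beta")
  coating_assay(mask, cells)
}

test_that("enrichment identities on constructed extreme assays", {
  withr::with_seed(1, {
    all_on <- half_coated_assay(on_coated = 1)
    none_on <- half_coated_assay(on_coated = 0)
  })
  expect_equal(occupancy_enrichment(all_on)$enrichment, 2.0)
  expect_equal(occupancy_enrichment(none_on)$enrichment, 0.0)
})

test_that("degenerate assays raise the contracted errors", {
  withr::with_seed(2, a <- half_coated_assay())
  expect_error(occupancy_enrichment(a, cell_type = "alpha"), "no cells")
  full <- a
  full$coated_mask[] <- TRUE
  expect_error(occupancy_enrichment(full), "degenerate")
  expect_error(avoidance_permutation_test(a, n_perm = 10), "n_perm")
})

test_that("CSR placement yields enrichment near 1 and complementarity holds", {
  assay <- simulate_coating_assay(0.4, occupancy_ratio = 1, n_cells = 2000,
                                  seed = 31)
  res <- occupancy_enrichment(assay)
  expect_gt(res$enrichment, 0.9)
  expect_lt(res$enrichment, 1.1)
  flipped <- coating_assay(!assay$coated_mask, assay$cells)
  res_off <- occupancy_enrichment(flipped)
  expect_equal(res$f_cells_on + res_off$f_cells_on, 1)
  # relabeling non-selected types does not change the beta-cell statistic
  relab <- assay
  relab$cells$cell_type[seq(1, 2000, by = 4)] <- "alpha"
  kept <- occupancy_enrichment(relab)
  on_kept <- isletmorph:::centroid_on_mask(
    relab$cells$x[relab$cells$cell_type == "beta"],
    relab$cells$y[relab$cells$cell_type == "beta"], relab$coated_mask)
  expect_equal(kept$f_cells_on, mean(on_kept))
})

test_that("the occupancy-ratio dial behaves as stated at its extremes", {
  excl <- simulate_coating_assay(0.5, occupancy_ratio = 0, n_cells = 300,
                                 seed = 8)
  expect_equal(occupancy_enrichment(excl)$enrichment, 0)
  a1 <- simulate_coating_assay(0.3, occupancy_ratio = 0.5, n_cells = 500,
                               seed = 9)
  a2 <- simulate_coating_assay(0.3, occupancy_ratio = 0.5, n_cells = 500,
                               seed = 9)
  expect_identical(a1$cells, a2$cells)
  expect_identical(a1$coated_mask, a2$coated_mask)
  expect_lt(mean(a1$coated_mask) - 0.3, 0.02)
})

test_that("strong avoidance is detected and the test is deterministic", {
  withr::with_seed(3, assay <- half_coated_assay(n = 100, on_coated = 0))
  res <- avoidance_permutation_test(assay, n_perm = 999, seed = 17)
  expect_lte(res$p, 0.01)
  expect_lt(res$z, -2)
  res2 <- avoidance_permutation_test(assay, n_perm = 999, seed = 17)
  expect_identical(c(res$z, res$p), c(res2$z, res2$p))
})

test_that("area-overlap membership variant tracks the centroid variant", {
  assay <- simulate_coating_assay(0.5, occupancy_ratio = 1, n_cells = 800,
                                  seed = 12)
  e_centroid <- occupancy_enrichment(assay)$enrichment
  e_area <- occupancy_enrichment(assay, membership = "area")$enrichment
  expect_lt(abs(e_centroid - e_area), 0.1)
})
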