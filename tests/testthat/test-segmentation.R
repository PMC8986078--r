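make_disk_image <- function(h, w, centers, r, value = 100) {
  img <- matrix(0, h, w)
  isletmorph:::draw_disks(img, centers[, 1], centers[, 2],
                          rep(r, nrow(centers)), rep(value, nrow(centers)))
}

test_that("two well-separated disks segment to two cells at their centers", {
  ctr <- rbind(c(30, 40), c(70, 40))
  img <- list(nuc = make_disk_image(80, 100, ctr, r = 8))
  seg <- segment_cells(img, segmentation_params(smoothing_sigma = 0,
                                                min_cell_area = 20,
                                                type_rules = NULL))
  expect_equal(nrow(seg$cells), 2)
  got <- seg$cells[order(seg$cells$x), ]
  expect_lt(max(abs(got$x - ctr[, 1])), 0.5)
  expect_lt(max(abs(got$y - ctr[, 2])), 0.5)
  expect_true(all(got$cell_type == "other"))
})

test_that("watershed splits two overlapping disks", {
  ctr <- rbind(c(40, 40), c(52, 40))  # centers 12 px apart, radius 8
  img <- list(nuc = make_disk_image(80, 100, ctr, r = 8))
  seg <- segment_cells(img, segmentation_params(smoothing_sigma = 0,
                                                min_cell_area = 20,
                                                type_rules = NULL))
  expect_equal(nrow(seg$cells), 2)
  expect_equal(max(seg$labels), 2L)
})

test_that("degenerate images give empty results, not errors", {
  img <- list(nuc = matrix(0, 40, 40))
  seg <- segment_cells(img, segmentation_params(type_rules = NULL))
  expect_equal(nrow(seg$cells), 0)
  expect_true(all(seg$labels == 0L))
  expect_error(segment_cells(list(dapi = matrix(0, 4, 4)),
                             segmentation_params(type_rules = NULL)),
               "lacks channel")
})

test_that("label masks partition foreground and respect the area bound", {
  pat <- simulate_islet(quick_config(seed = 2))
  rend <- render_islet(pat, noise_sd = 5, seed = 9)
  seg <- segment_cells(rend$image,
                       segmentation_params(smoothing_sigma = 1,
                                           min_cell_area = 15))
  expect_true(all(seg$labels >= 0))
  expect_setequal(unique(seg$labels[seg$labels > 0]), seg$cells$id)
  # every labelled pixel belongs to exactly one cell: areas sum to the
  # labelled foreground, which cannot exceed the whole image
  expect_equal(sum(seg$cells$area), sum(seg$labels > 0))
  expect_lte(sum(seg$labels > 0), length(seg$labels))
})

test_that("segmenting a noiseless sparse rendering recovers ground truth", {
  cfg <- sorting_config(n_alpha = 8, n_beta = 26, n_delta = 6,
                        domain_radius = 57, n_steps = 0, pixel_size = 0.5,
                        seed = 11)
  pat <- simulate_islet(cfg)
  rend <- render_islet(pat, noise_sd = 0)
  expect_equal(sort(unique(rend$labels[rend$labels > 0])), pat$cells$id)
  seg <- segment_cells(rend$image,
                       segmentation_params(smoothing_sigma = 1,
                                           min_cell_area = 60))
  dmat <- outer(seq_len(nrow(pat$cells)), seq_len(nrow(seg$cells)),
                function(i, j) sqrt((pat$cells$x[i] - seg$cells$x[j])^2 +
                                      (pat$cells$y[i] - seg$cells$y[j])^2))
  err <- apply(dmat, 1, min)
  expect_gte(mean(err < 1), 0.95)
  # marker-rule typing matches the simulated types
  match_idx <- apply(dmat, 1, which.min)
  expect_equal(seg$cells$cell_type[match_idx], pat$cells$cell_type)
})

test_that("noiseless single beta cell renders one component at its centroid", {
  cells <- cell_records(id = 1L, x = 30, y = 20, area = pi * 64,
                        cell_type = "beta")
  pat <- islet_pattern(cells, circle_poly(30, 20, 18), pixel_size = 1)
  rend <- render_islet(pat, noise_sd = 0)
  expect_equal(sum(rend$image$gcg), 0)
  lab <- t(EBImage::imageData(EBImage::bwlabel(
    EBImage::Image(t(rend$image$ins > 0)))))
  expect_equal(max(lab), 1)
  idx <- which(lab == 1, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 2] - 1) - 30), 0.5)
  expect_lt(abs(mean(idx[, 1] - 1) - 20), 0.5)
})

test_that("area fraction identities hold", {
  region <- matrix(FALSE, 20, 20)
  region[5:16, 5:16] <- TRUE
  expect_equal(area_fraction(region, region), 1.0)
  expect_equal(area_fraction(!region, region), 0.0)
  half <- region
  half[, 11:16] <- FALSE   # exactly half of the 12x12 region columns
  expect_equal(area_fraction(half, region), 0.5)
  expect_error(area_fraction(region, matrix(FALSE, 20, 20)), "empty")
  expect_error(area_fraction(region, matrix(TRUE, 10, 10)), "shape")
})
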