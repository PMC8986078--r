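test_that("configuration validation rejects bad inputs", {
  expect_error(sorting_config(n_alpha = -1), ">= 0")
  expect_error(sorting_config(n_alpha = 0, n_beta = 0, n_delta = 0), "at least one")
  expect_error(sorting_config(temperature = 0), "temperature")
  expect_error(sorting_config(frac_perturbed_beta = 1.2), "frac_perturbed")
  bad <- adhesion_matrix()
  bad[1, 2] <- 99
  expect_error(sorting_config(adhesion = bad), "symmetric")
  # more cells than the domain can hold
  expect_error(simulate_islet(sorting_config(n_beta = 500, domain_radius = 20,
                                             n_steps = 0, seed = 1)),
               "packing")
})

test_that("simulation conserves counts, keeps disks disjoint and is deterministic", {
  cfg <- quick_config(seed = 7)
  pat1 <- simulate_islet(cfg)
  pat2 <- simulate_islet(cfg)
  expect_identical(pat1$cells$x, pat2$cells$x)
  expect_identical(pat1$cells$y, pat2$cells$y)
  expect_equal(unname(table(pat1$cells$cell_type)[c("alpha", "beta", "delta")]),
               c(8, 26, 6), ignore_attr = TRUE)
  d <- as.matrix(dist(cbind(pat1$cells$x, pat1$cells$y)))
  diag(d) <- Inf
  expect_gte(min(d), 2 * cfg$cell_radius - 1e-9)
  # all inside the domain
  ctr <- cfg$domain_radius
  expect_true(all(sqrt((pat1$cells$x - ctr)^2 + (pat1$cells$y - ctr)^2) <=
                    cfg$domain_radius - cfg$cell_radius + 1e-9))
})

test_that("near-zero temperature anneals energy downhill on average", {
  cfg <- quick_config(n_steps = 400, seed = 5, temperature = 1e-4)
  e <- simulate_islet(cfg)$meta$energy
  # time-averaged energy over successive quarters is nonincreasing
  q <- split(e, cut(seq_along(e), 4, labels = FALSE))
  means <- vapply(q, mean, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("uniform adhesion with no repulsion gives composition matching shuffled labels", {
  adh0 <- matrix(-0.5, 3, 3,
                 dimnames = list(c("alpha", "beta", "delta"),
                                 c("alpha", "beta", "delta")))
  res <- vapply(1:10, function(s) {
    pat <- simulate_islet(sorting_config(adhesion = adh0, n_steps = 300,
                                         seed = s))
    obs <- measure_architecture(pat, boundary = "reconstruct")$core_pct_alpha
    shuf <- withr::with_seed(1000 + s, vapply(1:10, function(k) {
      cs <- pat$cells
      cs$cell_type <- sample(cs$cell_type)
      measure_architecture(
        islet_pattern(cs, pat$boundary, pixel_size = pat$pixel_size),
        boundary = "reconstruct")$core_pct_alpha
    }, numeric(1)))
    c(obs, mean(shuf))
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - mean(res[2, ])), 3)
})

test_that("beta-cohesive sorting pushes alpha cells out of the core relative to shuffled labels", {
  res <- vapply(1:6, function(s) {
    pat <- simulate_islet(sorting_config(n_steps = 4000, seed = s))
    obs <- measure_architecture(pat, boundary = "reconstruct")$core_pct_alpha
    shuf <- withr::with_seed(2000 + s, vapply(1:10, function(k) {
      cs <- pat$cells
      cs$cell_type <- sample(cs$cell_type)
      measure_architecture(
        islet_pattern(cs, pat$boundary, pixel_size = pat$pixel_size),
        boundary = "reconstruct")$core_pct_alpha
    }, numeric(1)))
    c(obs, mean(shuf))
  }, numeric(2))
  expect_lt(mean(res[1, ]), mean(res[2, ]))
})

test_that("shipped fixture configs load and differ only in the perturbation", {
  ctl <- read_sorting_config(system.file("extdata", "control.yaml",
                                         package = "isletmorph"))
  nicd <- read_sorting_config(system.file("extdata", "nicd.yaml",
                                          package = "isletmorph"))
  expect_identical(ctl$adhesion, nicd$adhesion)
  expect_identical(ctl$n_beta, nicd$n_beta)
  expect_equal(ctl$repulsion_beta, 0)
  expect_gt(nicd$repulsion_beta, 0)
  expect_equal(nicd$frac_perturbed_beta, 1)
})
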