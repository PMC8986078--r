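test_that("gene-set scores reduce to member means", {
  mat <- tibble::tibble(cell = c("c1", "c2"), group = c("H", "MI"),
                        g1 = c(1, 2), g2 = c(3, 4), g3 = c(10, 20))
  sc <- gene_set_score(mat, gene_set("pair", c("g1", "g2")))
  expect_equal(sc$scores$score, c(2, 3))
  single <- gene_set_score(mat, gene_set("solo", "g3"))
  expect_equal(single$scores$score, mat$g3)
  withdrop <- gene_set_score(mat, gene_set("partial", c("g1", "absent")))
  expect_equal(withdrop$members_dropped, "absent")
  expect_error(gene_set_score(mat, gene_set("none", c("zz", "yy"))),
               "no member")
})

test_that("random-matrix scores equal a brute-force row mean", {
  mat <- simulate_activity_matrix(10, 10, component_features = 8, delta = 1,
                                  rho = 0.4, seed = 3)
  members <- c("comp_2", "comp_5", "comp_7")
  sc <- gene_set_score(mat, gene_set("s", members))
  brute <- apply(as.matrix(mat[, members]), 1, mean)
  expect_equal(sc$scores$score, unname(brute))
  gm <- sc$group_means
  expect_equal(gm$mean_score[gm$group == "H"],
               mean(brute[mat$group == "H"]))
})

test_that("enrichment score endpoints match hand-computed running sums", {
  ranking <- tibble::tibble(feature = c("a", "b", "c", "d"),
                            score = c(4, 3, 2, 1))
  top <- preranked_enrichment(ranking, gene_set("top", "a"), weight = 0,
                              n_perm = 199, seed = 1)
  expect_equal(top$es, 1)
  bottom <- preranked_enrichment(ranking, gene_set("bottom", "d"), weight = 0,
                                 n_perm = 199, seed = 1)
  expect_equal(bottom$es, -1)
  expect_error(preranked_enrichment(ranking, gene_set("all", ranking$feature)),
               "whole ranking")
  dup <- tibble::tibble(feature = c("a", "a", "b"), score = 3:1)
  expect_error(preranked_enrichment(dup, gene_set("s", "b")), "duplicate")
})

test_that("weight-0 ES equals the brute-force oracle on random instances", {
  withr::with_seed(5, {
    for (k in 1:100) {
      scores <- sort(rnorm(50), decreasing = TRUE)
      feats <- paste0("f", 1:50)
      members <- sample(feats, 5)
      res <- preranked_enrichment(tibble::tibble(feature = feats, score = scores),
                                  gene_set("s", members), weight = 0,
                                  n_perm = 0, seed = 1)
      expect_equal(res$es, brute_force_es(feats, scores, members, weight = 0))
    }
  })
})

test_that("weighted ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(6, {
    for (k in 1:20) {
      scores <- sort(rnorm(60), decreasing = TRUE)
      feats <- paste0("g", 1:60)
      members <- sample(feats, 7)
      res <- preranked_enrichment(tibble::tibble(feature = feats, score = scores),
                                  gene_set("s", members), weight = 1,
                                  n_perm = 0, seed = 1)
      ref <- fgsea::calcGseaStat(stats::setNames(scores, feats),
                                 which(feats %in% members),
                                 gseaParam = 1, scoreType = "std")
      expect_equal(res$es, ref, tolerance = 1e-8)
    }
  })
})

test_that("weight-0 ES is invariant to monotone rescaling of the scores", {
  withr::with_seed(8, {
    scores <- sort(rexp(40), decreasing = TRUE)
    feats <- paste0("f", 1:40)
    members <- sample(feats, 6)
  })
  r1 <- preranked_enrichment(tibble::tibble(feature = feats, score = scores),
                             gene_set("s", members), weight = 0, n_perm = 99,
                             seed = 2)
  r2 <- preranked_enrichment(tibble::tibble(feature = feats,
                                            score = scores^3 + 5),
                             gene_set("s", members), weight = 0, n_perm = 99,
                             seed = 2)
  expect_equal(r1$es, r2$es)
  expect_equal(r1$p, r2$p)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(0, 1, 2, 3)
  expect_equal(regulator_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(regulator_correlation(x, -x)$r, -1)
  tri <- regulator_correlation(c(0, 1, 2), c(0, 1, 0))
  expect_equal(tri$r, 0)
  expect_error(regulator_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(regulator_correlation(1:2, 1:2), "at least 3")
})

test_that("GMT round trip preserves sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA$members, c("g1", "g2", "g3"))
})
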