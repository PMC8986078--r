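# shared builders for small, fast test objects

adhesion_matrix <- function(jaa = -0.3, jbb = -2, jab = -0.4) {
  tps <- c("alpha", "beta", "delta")
  m <- matrix(jaa, 3, 3, dimnames = list(tps, tps))
  m["beta", "beta"] <- jbb
  m["alpha", "beta"] <- m["beta", "alpha"] <- jab
  m["beta", "delta"] <- m["delta", "beta"] <- jab
  m
}

# a quick-to-anneal small islet config for unit tests (not the calibrated
# study conditions, which live in inst/extdata/*.yaml)
quick_config <- function(..., n_steps = 200, seed = 1) {
  sorting_config(n_alpha = 8, n_beta = 26, n_delta = 6, domain_radius = 40,
                 n_steps = n_steps, seed = seed, ...)
}

# uniform disk of labelled points wrapped as an islet pattern
disk_pattern <- function(n = 60, radius = 100, seed = 1, cell_area = 38.5) {
  withr::with_seed(seed, {
    r <- radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cells <- cell_records(
      id = seq_len(n), x = radius + r * cos(th), y = radius + r * sin(th),
      area = cell_area,
      cell_type = sample(c("alpha", "beta", "delta"), n, replace = TRUE))
    islet_pattern(cells, circle_poly(radius, radius, radius), pixel_size = 1)
  })
}

circle_poly <- function(cx, cy, r, k = 180) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# independent brute-force running-sum enrichment score (the oracle kept
# deliberately naive: walk every rank position)
brute_force_es <- function(ranked_features, scores, members, weight = 0) {
  hit <- ranked_features %in% members
  nh <- sum(hit)
  n <- length(ranked_features)
  w <- abs(scores)^weight
  inc <- w * hit / sum(w[hit])
  dec <- (!hit) / (n - nh)
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}
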