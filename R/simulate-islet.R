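#' Configuration for the differential-adhesion islet sorting simulator
#'
#' The simulator places alpha, beta and delta cells as hard disks in a
#' circular domain and relaxes the configuration by Metropolis Monte Carlo
#' under pairwise contact energies. Lower adhesion energy means a more
#' adhesive type pair; making beta-beta contacts the most favourable
#' reproduces the murine mantle-core architecture (beta core, alpha/delta
#' mantle). A nonnegative `repulsion_beta` is added to every contact that
#' involves a "perturbed" beta cell, modelling cell-autonomous
#' Notch-driven ephrin contact repulsion; perturbed cells are flagged at
#' initialization and keep the flag.
#'
#' @param n_alpha,n_beta,n_delta cell counts (nonnegative integers, at
#'   least one cell in total).
#' @param domain_radius islet domain radius in micrometres.
#' @param cell_radius hard-disk cell radius in micrometres.
#' @param adhesion symmetric 3x3 type-pair energy table (dimensionless;
#'   rows/columns named alpha, beta, delta; lower = more adhesive).
#' @param repulsion_beta extra pairwise energy (>= 0) for contacts
#'   involving a perturbed beta cell.
#' @param frac_perturbed_beta fraction of beta cells flagged perturbed,
#'   in \[0, 1\].
#' @param temperature Metropolis temperature (dimensionless, > 0).
#' @param n_steps number of Monte Carlo sweeps (one attempted move per
#'   cell per sweep).
#' @param pixel_size micrometres per pixel for the emitted pattern.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `sorting_config`.
#' @export
sorting_config <- function(n_alpha = 20, n_beta = 70, n_delta = 10,
                           domain_radius = 57, cell_radius = 3.5,
                           adhesion = default_adhesion(),
                           repulsion_beta = 0, frac_perturbed_beta = 0,
                           temperature = 0.8, n_steps = 15000,
                           pixel_size = 1, seed = NULL) {
  adhesion <- as_adhesion_matrix(adhesion)
  cfg <- structure(
    list(n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
         n_delta = as.integer(n_delta), domain_radius = domain_radius,
         cell_radius = cell_radius, adhesion = adhesion,
         repulsion_beta = repulsion_beta,
         frac_perturbed_beta = frac_perturbed_beta,
         temperature = temperature, n_steps = as.integer(n_steps),
         pixel_size = pixel_size,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sorting_config")
  validate_sorting_config(cfg)
}

#' @rdname sorting_config
#' @export
default_adhesion <- function() {
  # beta-beta contacts strongly favourable, beta-nonbeta weakly so, and
  # non-beta pairs weaker still: the classic differential-adhesion ordering
  # that expels alpha/delta cells to the islet surface
  m <- matrix(-0.3, 3, 3, dimnames = list(c("alpha", "beta", "delta"),
                                          c("alpha", "beta", "delta")))
  m["beta", "beta"] <- -2
  m["alpha", "beta"] <- m["beta", "alpha"] <- -0.4
  m["beta", "delta"] <- m["delta", "beta"] <- -0.4
  m
}

as_adhesion_matrix <- function(adhesion) {
  tps <- c("alpha", "beta", "delta")
  if (is.list(adhesion)) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(tps, tps))
    for (a in tps) for (b in tps) {
      v <- adhesion[[a]][[b]]
      if (!is.null(v)) m[a, b] <- v
    }
    adhesion <- m
  }
  stopifnot(is.matrix(adhesion), dim(adhesion) == c(3, 3))
  if (is.null(dimnames(adhesion))) dimnames(adhesion) <- list(tps, tps)
  adhesion <- adhesion[tps, tps]
  if (anyNA(adhesion)) abort("adhesion table has missing entries")
  if (!isTRUE(all.equal(adhesion, t(adhesion)))) {
    abort("adhesion table must be symmetric")
  }
  adhesion
}

validate_sorting_config <- function(cfg) {
  with(cfg, {
    if (n_alpha < 0 || n_beta < 0 || n_delta < 0) abort("cell counts must be >= 0")
    if (n_alpha + n_beta + n_delta < 1) abort("need at least one cell")
    if (domain_radius <= 0 || cell_radius <= 0) abort("radii must be > 0")
    if (repulsion_beta < 0) abort("repulsion_beta must be >= 0")
    if (frac_perturbed_beta < 0 || frac_perturbed_beta > 1) {
      abort("frac_perturbed_beta must lie in [0, 1]")
    }
    if (temperature <= 0) abort("temperature must be > 0")
    if (n_steps < 0) abort("n_steps must be >= 0")
  })
  cfg
}

#' Read a sorting-simulator configuration from YAML
#'
#' @param path path to a YAML file whose keys are [sorting_config()]
#'   arguments; `adhesion` is a nested map type -> type -> energy.
#' @return A `sorting_config`.
#' @export
read_sorting_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sorting_config))
  unknown <- setdiff(names(raw), c(known, "name", "notes"))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(sorting_config, raw[intersect(names(raw), known)])
}

# Random sequential placement of non-overlapping disks in the domain.
place_cells_rsa <- function(n, domain_radius, cell_radius, max_tries = 20000L) {
  rmax <- domain_radius - cell_radius
  if (rmax <= 0 && n > 0) abort("domain too small for even one cell (packing error)")
  xy <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "could not pack %d cells of radius %g in a domain of radius %g (packing error)",
        n, cell_radius, domain_radius))
    }
    u <- runif(1); th <- runif(1, 0, 2 * pi)
    r <- rmax * sqrt(u)
    cand <- c(r * cos(th), r * sin(th))
    if (placed > 0L) {
      d2 <- (xy[seq_len(placed), 1] - cand[1])^2 + (xy[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < (2 * cell_radius)^2) next
    }
    placed <- placed + 1L
    xy[placed, ] <- cand
    tries <- 0L
  }
  xy
}

#' Simulate a sorted islet point pattern
#'
#' Cells start from uniform random non-overlapping positions and undergo
#' `n_steps` Metropolis sweeps of single-cell Gaussian displacement moves
#' (step sd = `cell_radius / 2`), with moves rejected when they overlap
#' another cell or leave the circular domain, and otherwise accepted with
#' probability `min(1, exp(-dE / temperature))`. Contact energies act
#' between pairs closer than 2.5 cell radii.
#'
#' @param config a [sorting_config()].
#' @return An [islet_pattern()] in pixel coordinates (domain centre at
#'   `domain_radius / pixel_size`); `meta` records the seed, the config
#'   and the per-sweep total-energy trace. Cell areas are the disk areas
#'   in pixels^2; perturbed beta cells carry `perturbed = TRUE`.
#' @export
simulate_islet <- function(config) {
  stopifnot(inherits(config, "sorting_config"))
  n <- config$n_alpha + config$n_beta + config$n_delta
  with_seed(config$seed, {
    types <- c(rep("alpha", config$n_alpha), rep("beta", config$n_beta),
               rep("delta", config$n_delta))
    perturbed <- rep(FALSE, n)
    n_pert <- round(config$frac_perturbed_beta * config$n_beta)
    if (n_pert > 0) {
      beta_idx <- which(types == "beta")
      perturbed[sample(beta_idx, n_pert)] <- TRUE
    }
    xy <- place_cells_rsa(n, config$domain_radius, config$cell_radius)
    type_code <- match(types, c("alpha", "beta", "delta")) - 1L
    res <- sorting_mc(xy, type_code, perturbed, config$adhesion,
                      config$repulsion_beta, config$domain_radius,
                      config$cell_radius, config$temperature,
                      config$n_steps, config$cell_radius / 2)
    ps <- config$pixel_size
    r_px <- config$cell_radius / ps
    cells <- cell_records(
      id = seq_len(n),
      x = (res$xy[, 1] + config$domain_radius) / ps,
      y = (res$xy[, 2] + config$domain_radius) / ps,
      area = pi * r_px^2,
      cell_type = types,
      perturbed = perturbed)
    boundary <- circle_polygon(config$domain_radius / ps,
                               config$domain_radius / ps,
                               config$domain_radius / ps)
    islet_pattern(cells, boundary, pixel_size = ps,
                  meta = list(seed = config$seed, config = config,
                              energy = res$energy))
  })
}
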