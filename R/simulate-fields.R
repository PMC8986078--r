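#' Simulate a pseudoislet aggregation field
#'
#' Cell centres are drawn from a Neyman-Scott cluster process: cluster
#' centres uniform over the field, offspring displaced from a uniformly
#' chosen centre by an isotropic Gaussian of sd `cluster_sd` (offspring
#' falling outside the field are redrawn so the count is exact). Small
#' `cluster_sd` with one cluster emulates a well-formed pseudoislet;
#' large `cluster_sd` emulates failed aggregation of dispersed cells.
#'
#' @param n_cells number of cells.
#' @param n_clusters number of cluster centres (>= 1, <= n_cells).
#' @param cluster_sd offspring dispersion around the centre, pixels (> 0).
#' @param field_size side length of the square field, pixels.
#' @param cell_radius rendered disk radius, pixels.
#' @param seed integer seed.
#' @return A list with `points` (tibble `x`, `y` in 0-based pixels),
#'   `image` (logical matrix of rendered disks) and the parameters.
#' @export
simulate_pseudoislet_field <- function(n_cells, n_clusters, cluster_sd,
                                       field_size = 512, cell_radius = 4,
                                       seed = NULL) {
  if (n_clusters < 1) abort("n_clusters must be >= 1")
  if (n_clusters > n_cells) abort("n_clusters may not exceed n_cells")
  if (cluster_sd <= 0) abort("cluster_sd must be > 0")
  with_seed(seed, {
    centres <- matrix(runif(2 * n_clusters, 0, field_size), ncol = 2)
    parent <- sample.int(n_clusters, n_cells, replace = TRUE)
    pts <- matrix(NA_real_, n_cells, 2)
    todo <- seq_len(n_cells)
    while (length(todo) > 0) {
      prop <- centres[parent[todo], , drop = FALSE] +
        matrix(rnorm(2 * length(todo), 0, cluster_sd), ncol = 2)
      ok <- prop[, 1] >= 0 & prop[, 1] < field_size &
            prop[, 2] >= 0 & prop[, 2] < field_size
      pts[todo[ok], ] <- prop[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    img <- matrix(0, field_size, field_size)
    img <- draw_disks(img, pts[, 1], pts[, 2], rep(cell_radius, n_cells),
                      rep(1, n_cells)) > 0.5
    list(points = tibble(x = pts[, 1], y = pts[, 2]), image = img,
         n_cells = n_cells, n_clusters = n_clusters, cluster_sd = cluster_sd,
         field_size = field_size, cell_radius = cell_radius, seed = seed)
  })
}

#' Bundle a coated-surface assay
#'
#' @param coated_mask logical matrix (rows = y, cols = x): TRUE where the
#'   surface is ligand-coated.
#' @param cells cell table ([cell_records()]).
#' @param pixel_size micrometres per pixel.
#' @param meta optional provenance list.
#' @return An object of class `coating_assay`.
#' @export
coating_assay <- function(coated_mask, cells, pixel_size = 1, meta = list()) {
  stopifnot(is.matrix(coated_mask), is.logical(coated_mask))
  validate_cells(cells)
  structure(list(coated_mask = coated_mask, cells = as_tibble(cells),
                 pixel_size = pixel_size, meta = meta),
            class = "coating_assay")
}

#' @export
print.coating_assay <- function(x, ...) {
  cat(sprintf("<coating_assay> %dx%d field, coated fraction %.3f, %d cells\n",
              nrow(x$coated_mask), ncol(x$coated_mask),
              mean(x$coated_mask), nrow(x$cells)))
  invisible(x)
}

#' Simulate a ligand-coated surface assay
#'
#' The coated region is a random blob field: white noise smoothed with a
#' Gaussian kernel and thresholded at the quantile giving the requested
#' areal fraction. Cells are placed by rejection sampling so the odds of
#' landing on coated versus uncoated area equal `occupancy_ratio`
#' (1 = no preference, < 1 = avoidance, 0 = complete exclusion).
#'
#' @param coated_fraction target coated areal fraction, strictly in (0, 1).
#' @param occupancy_ratio relative probability of a cell landing on coated
#'   vs uncoated area (>= 0).
#' @param n_cells number of cells to place.
#' @param field_size side length of the square field, pixels.
#' @param blob_sigma smoothing sd controlling blob size, pixels.
#' @param cell_type type assigned to the placed cells.
#' @param seed integer seed.
#' @return A [coating_assay()].
#' @export
simulate_coating_assay <- function(coated_fraction, occupancy_ratio, n_cells,
                                   field_size = 256, blob_sigma = 8,
                                   cell_type = "beta", seed = NULL) {
  if (coated_fraction <= 0 || coated_fraction >= 1) {
    abort("coated_fraction must lie strictly in (0, 1)")
  }
  if (occupancy_ratio < 0) abort("occupancy_ratio must be >= 0")
  if (n_cells < 1) abort("n_cells must be >= 1")
  with_seed(seed, {
    noise <- matrix(rnorm(field_size^2), field_size, field_size)
    smooth <- t(EBImage::imageData(
      EBImage::gblur(EBImage::Image(t(noise)), sigma = blob_sigma)))
    mask <- smooth >= quantile(smooth, 1 - coated_fraction)
    p_on <- if (occupancy_ratio <= 1) occupancy_ratio else 1
    p_off <- if (occupancy_ratio <= 1) 1 else 1 / occupancy_ratio
    xs <- ys <- numeric(0)
    while (length(xs) < n_cells) {
      m <- max(2L * (n_cells - length(xs)), 64L)
      px <- runif(m, 0, field_size)
      py <- runif(m, 0, field_size)
      on <- mask[cbind(floor(py) + 1L, floor(px) + 1L)]
      keep <- runif(m) < ifelse(on, p_on, p_off)
      xs <- c(xs, px[keep])
      ys <- c(ys, py[keep])
    }
    xs <- xs[seq_len(n_cells)]; ys <- ys[seq_len(n_cells)]
    cells <- cell_records(id = seq_len(n_cells), x = xs, y = ys,
                          area = pi * 4^2, cell_type = cell_type)
    coating_assay(mask, cells,
                  meta = list(coated_fraction = coated_fraction,
                              occupancy_ratio = occupancy_ratio, seed = seed))
  })
}

#' Simulate a per-cell regulator-activity and component-expression matrix
#'
#' Emulates the statistical structure of a healthy (H) versus
#' metabolically inflexible (MI) beta-cell comparison: regulator activity
#' is standard normal in H cells and shifted by `delta` in MI cells; each
#' component feature is `rho * regulator + sqrt(1 - rho^2) * noise`, so
#' the within-group Pearson correlation with the regulator is `rho` and
#' group shifts propagate to the components (MI component mean
#' `rho * delta`).
#'
#' @param n_H,n_MI cells per group (>= 3).
#' @param component_features character vector of component feature names,
#'   or an integer count (names `comp_1`, ...).
#' @param delta regulator group shift (MI minus H), in sd units.
#' @param rho within-group Pearson correlation of each component with the
#'   regulator, |rho| < 1.
#' @param seed integer seed.
#' @return A tibble with columns `cell`, `group` ("H"/"MI"),
#'   `regulator`, and one column per component feature; attribute
#'   `feature_kind` labels the regulator "activity" and components
#'   "expression".
#' @export
simulate_activity_matrix <- function(n_H, n_MI, component_features = 5,
                                     delta = 1, rho = 0.5, seed = NULL) {
  if (n_H < 3 || n_MI < 3) abort("need at least 3 cells per group")
  if (abs(rho) >= 1) abort("|rho| must be < 1")
  if (is.numeric(component_features) && length(component_features) == 1) {
    component_features <- paste0("comp_", seq_len(component_features))
  }
  with_seed(seed, {
    n <- n_H + n_MI
    group <- c(rep("H", n_H), rep("MI", n_MI))
    reg <- rnorm(n) + ifelse(group == "MI", delta, 0)
    comp <- vapply(component_features, function(f) {
      rho * reg + sqrt(1 - rho^2) * rnorm(n)
    }, numeric(n))
    out <- tibble(cell = paste0("cell_", seq_len(n)), group = group,
                  regulator = reg)
    out <- dplyr::bind_cols(out, as_tibble(comp))
    attr(out, "feature_kind") <- c(
      regulator = "activity",
      stats::setNames(rep("expression", length(component_features)),
                      component_features))
    out
  })
}
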