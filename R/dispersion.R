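#' Dispersion degree of a point set
#'
#' The aggregation statistic for pseudoislet assays: all pairwise
#' Euclidean centroid distances are computed, normalized by `d_max`
#' (distances beyond `d_max` clipped to 1), and summarized by the exact
#' area under the right-continuous empirical CDF of the normalized
#' distances over \[0, 1\]. The dispersion degree is `1 - auc`, which for
#' a step CDF equals the mean normalized clipped distance: tight
#' aggregates have small distances, an early-rising CDF, AUC near 1 and
#' dispersion near 0; scattered cells approach 1.
#'
#' @param points a data frame with `x`, `y` columns or a two-column
#'   matrix of coordinates (any length unit, consistently with `d_max`).
#' @param d_max normalization distance (> 0). Default: the diagonal of
#'   the points' bounding box; pass the image diagonal to normalize
#'   across fields of the same size.
#' @return An object of class `dispersion_result` with elements
#'   `distances` (raw pairwise distances), `d_max`, `auc`,
#'   `dispersion_degree`, `n`.
#' @export
dispersion_degree <- function(points, d_max = NULL) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 2) abort("dispersion degree needs at least 2 points")
  if (is.null(d_max)) {
    d_max <- sqrt(diff(range(pts[, 1]))^2 + diff(range(pts[, 2]))^2)
    if (d_max <= 0) d_max <- 1  # all points coincident: any scale works
  }
  if (d_max <= 0) abort("d_max must be > 0")
  d <- as.numeric(stats::dist(pts))
  t_norm <- pmin(d / d_max, 1)
  # exact integral of the step CDF on [0,1]: 1 - mean of the support
  auc <- 1 - mean(t_norm)
  structure(list(distances = d, d_max = d_max, auc = auc,
                 dispersion_degree = 1 - auc, n = n),
            class = "dispersion_result")
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    cbind(points$x, points$y)
  } else if (is.matrix(points) && ncol(points) == 2) {
    points
  } else {
    abort("points must be a data frame with x/y columns or a 2-column matrix")
  }
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> n = %d, d_max = %.4g, auc = %.4f, dispersion degree = %.4f\n",
              x$n, x$d_max, x$auc, x$dispersion_degree))
  invisible(x)
}

#' @export
tidy.dispersion_result <- function(x, ...) {
  t_sorted <- sort(pmin(x$distances / x$d_max, 1))
  tibble(t = t_sorted, cdf = seq_along(t_sorted) / length(t_sorted))
}

#' @export
glance.dispersion_result <- function(x, ...) {
  tibble(n = x$n, d_max = x$d_max, auc = x$auc,
         dispersion_degree = x$dispersion_degree)
}

#' Dispersion degree of a binary field image
#'
#' Segments a binary (or already thresholded) image by watershed and runs
#' [dispersion_degree()] on the recovered centroids, normalizing by the
#' image diagonal.
#'
#' @param image numeric or logical matrix (rows = y, cols = x).
#' @param min_cell_area minimum object area retained, pixels^2.
#' @return A `dispersion_result`.
#' @export
dispersion_from_image <- function(image, min_cell_area = 20) {
  img <- list(field = image * 1)
  seg <- segment_cells(img, segmentation_params(
    threshold_method = "fixed", fixed_threshold = 0.5, smoothing_sigma = 0,
    min_cell_area = min_cell_area, seg_channel = "field", type_rules = NULL))
  if (nrow(seg$cells) < 2) abort("fewer than 2 cells segmented from the image")
  dispersion_degree(seg$cells, d_max = sqrt(nrow(image)^2 + ncol(image)^2))
}
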