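#' Construct a table of per-cell records
#'
#' A cell record is one segmented (or simulated) cell: an integer id, a
#' centroid in 0-based pixel coordinates (x rightward, y downward,
#' pixel-center convention), an area in pixels^2, an assigned endocrine
#' type, and optionally one `mean_<channel>` column per imaging channel.
#'
#' @param id integer cell ids (unique).
#' @param x,y centroid coordinates in pixels (0-based, pixel-center).
#' @param area cell areas in pixels^2 (> 0).
#' @param cell_type one of `"alpha"`, `"beta"`, `"delta"`, `"other"`.
#' @param ... further per-cell columns (e.g. `mean_ins`, `perturbed`).
#' @return A tibble with one row per cell.
#' @export
cell_records <- function(id, x, y, area, cell_type = "other", ...) {
  cells <- tibble(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
                  area = as.numeric(area), cell_type = as.character(cell_type), ...)
  validate_cells(cells)
  cells
}

cell_types_known <- c("alpha", "beta", "delta", "other")

validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells))
  req <- c("id", "x", "y", "area", "cell_type")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("cell table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cells$id)) abort("cell ids must be unique")
  if (nrow(cells) > 0 && any(cells$area <= 0)) abort("cell areas must be > 0")
  if (!all(cells$cell_type %in% cell_types_known)) {
    abort("cell_type must be one of alpha/beta/delta/other")
  }
  chan <- grep("^mean_", names(cells), value = TRUE)
  for (cc in chan) {
    if (nrow(cells) > 0 && any(cells[[cc]] < 0)) abort("channel means must be >= 0")
  }
  invisible(cells)
}

#' Bundle cells with an islet boundary into an islet pattern
#'
#' The islet pattern is the unit of architecture analysis: a table of cell
#' records plus the islet boundary — either a polygon (two-column matrix of
#' 0-based pixel vertices) or a logical mask — and the pixel size in
#' micrometres per pixel. Every cell centroid must lie inside the boundary.
#'
#' @param cells a cell table as built by [cell_records()].
#' @param boundary a closed polygon (n x 2 numeric matrix, columns x, y) or
#'   a logical matrix mask (rows = y, cols = x).
#' @param pixel_size micrometres per pixel.
#' @param meta optional named list of provenance metadata (seeds, configs).
#' @return An object of class `islet_pattern`.
#' @export
islet_pattern <- function(cells, boundary, pixel_size = 1, meta = list()) {
  validate_cells(cells)
  if (is.matrix(boundary) && !is.logical(boundary)) {
    stopifnot(ncol(boundary) == 2, nrow(boundary) >= 3)
  } else if (is.matrix(boundary) && is.logical(boundary)) {
    if (!any(boundary)) abort("boundary mask is empty")
  } else {
    abort("boundary must be a polygon matrix or a logical mask")
  }
  stopifnot(pixel_size > 0)
  pat <- structure(
    list(cells = as_tibble(cells), boundary = boundary,
         pixel_size = pixel_size, meta = meta),
    class = "islet_pattern")
  if (nrow(cells) > 0) {
    inside <- points_inside_boundary(cells$x, cells$y, boundary)
    if (!all(inside)) {
      abort(sprintf("%d cell centroid(s) lie outside the islet boundary",
                    sum(!inside)))
    }
  }
  pat
}

#' @export
print.islet_pattern <- function(x, ...) {
  btype <- if (is.logical(x$boundary)) "mask" else "polygon"
  cat(sprintf("<islet_pattern> %d cells, %s boundary, %.3g um/px\n",
              nrow(x$cells), btype, x$pixel_size))
  print(dplyr::count(x$cells, .data$cell_type))
  invisible(x)
}

#' @export
tidy.islet_pattern <- function(x, ...) x$cells

points_inside_boundary <- function(x, y, boundary) {
  if (is.logical(boundary)) {
    i <- floor(y) + 1L
    j <- floor(x) + 1L
    ok <- i >= 1L & i <= nrow(boundary) & j >= 1L & j <= ncol(boundary)
    ins <- rep(FALSE, length(x))
    ins[ok] <- boundary[cbind(i[ok], j[ok])]
    ins
  } else {
    point_in_polygon(x, y, boundary)
  }
}

# Even-odd ray casting; points on an edge count as inside (tolerance via >=).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((ys[k] > py) != (ye[k] > py))
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Exact minimum distance from each point to the polygon outline.
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
  dmin <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    vx <- bx[k] - ax[k]; vy <- by[k] - ay[k]
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      d2 <- (px - ax[k])^2 + (py - ay[k])^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax[k]) * vx + (py - ay[k]) * vy) / len2))
      d2 <- (px - (ax[k] + t * vx))^2 + (py - (ay[k] + t * vy))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# Regular polygon approximating a circle (used for simulated islet domains).
circle_polygon <- function(cx, cy, r, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Derive an islet boundary mask from cell positions alone
#'
#' When only segmented cells are available the islet outline is
#' reconstructed as the morphological closing of the union of cell disks,
#' hole-filled. The closing radius defaults to two cell radii so that gaps
#' between touching neighbours are absorbed without inflating the outline.
#'
#' @param cells cell table with `x`, `y`, `area` (pixels^2).
#' @param closing_radius structuring-element radius in pixels; default
#'   2 x median equivalent cell radius.
#' @param pad margin of background pixels around the mask.
#' @return A logical matrix mask (rows = y, cols = x).
#' @export
boundary_from_cells <- function(cells, closing_radius = NULL, pad = 4L) {
  validate_cells(cells)
  if (nrow(cells) == 0) abort("cannot derive a boundary from zero cells")
  r_cell <- sqrt(cells$area / pi)
  closing_radius <- closing_radius %||% (2 * median(r_cell))
  w <- ceiling(max(cells$x + r_cell)) + pad + 1L
  h <- ceiling(max(cells$y + r_cell)) + pad + 1L
  img <- matrix(0, nrow = h, ncol = w)
  img <- draw_disks(img, cells$x, cells$y, r_cell, rep(1, nrow(cells)))
  eb <- EBImage::Image(t(img))
  kern <- EBImage::makeBrush(2L * ceiling(closing_radius) + 1L, shape = "disc")
  closed <- EBImage::closing(eb, kern)
  filled <- EBImage::fillHull(closed)
  t(EBImage::imageData(filled)) > 0.5
}

# Paint filled disks into a matrix (rows = y, cols = x; 0-based centers).
# Later disks overwrite earlier ones where they overlap.
draw_disks <- function(img, cx, cy, r, value) {
  h <- nrow(img); w <- ncol(img)
  for (k in seq_along(cx)) {
    j0 <- max(1L, floor(cx[k] - r[k]) + 1L); j1 <- min(w, ceiling(cx[k] + r[k]) + 1L)
    i0 <- max(1L, floor(cy[k] - r[k]) + 1L); i1 <- min(h, ceiling(cy[k] + r[k]) + 1L)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    dx2 <- ((jj - 1) - cx[k])^2
    dy2 <- ((ii - 1) - cy[k])^2
    hit <- outer(dy2, dx2, `+`) <= r[k]^2
    sub <- img[ii, jj, drop = FALSE]
    sub[hit] <- value[k]
    img[ii, jj] <- sub
  }
  img
}
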