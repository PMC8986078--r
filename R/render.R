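#' Render an islet pattern to a multi-channel image with ground truth
#'
#' Each cell is drawn as a filled disk of the given amplitude into every
#' channel whose spec lists its type, with optional additive Gaussian
#' intensity noise (clamped at zero). The true instance label mask is
#' returned alongside for segmentation benchmarking.
#'
#' @param pattern an [islet_pattern()].
#' @param channels named list mapping channel name to the cell types drawn
#'   in it, e.g. `list(ins = "beta", gcg = "alpha", sst = "delta",
#'   nuc = c("alpha", "beta", "delta"))`.
#' @param amplitude in-disk intensity (arbitrary units).
#' @param noise_sd Gaussian noise sd in intensity units.
#' @param seed integer seed for the noise.
#' @return A list with `image` (named list of numeric matrices, rows = y,
#'   cols = x), `labels` (integer matrix; background 0, cell ids > 0) and
#'   `pattern`.
#' @export
render_islet <- function(pattern,
                         channels = list(ins = "beta", gcg = "alpha",
                                         sst = "delta",
                                         nuc = c("alpha", "beta", "delta")),
                         amplitude = 100, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(pattern, "islet_pattern"))
  dims <- render_dims(pattern$boundary)
  cells <- pattern$cells
  labels <- matrix(0L, nrow = dims[1], ncol = dims[2])
  r_px <- sqrt(cells$area / pi)
  if (nrow(cells) > 0) {
    labels <- draw_disks(labels, cells$x, cells$y, r_px, cells$id)
  }
  with_seed(seed, {
    image <- lapply(channels, function(types) {
      ch <- matrix(0, nrow = dims[1], ncol = dims[2])
      sel <- cells$cell_type %in% types
      if (any(sel)) {
        ch <- draw_disks(ch, cells$x[sel], cells$y[sel], r_px[sel],
                         rep(amplitude, sum(sel)))
      }
      if (noise_sd > 0) {
        ch <- pmax(ch + matrix(rnorm(length(ch), 0, noise_sd), nrow = dims[1]), 0)
      }
      ch
    })
    list(image = image, labels = labels, pattern = pattern)
  })
}

render_dims <- function(boundary) {
  if (is.logical(boundary)) {
    dim(boundary)
  } else {
    c(ceiling(max(boundary[, 2])) + 2L, ceiling(max(boundary[, 1])) + 2L)
  }
}
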