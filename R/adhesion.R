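#' Occupancy enrichment of cells on a coated region
#'
#' Algorithm 1 of the coated-surface avoidance analysis: the fraction of
#' selected-type cells lying on coated pixels, normalized to the coated
#' areal fraction. Enrichment 1 means no preference; below 1, avoidance.
#' Membership is by centroid pixel by default (the centroid `(x, y)`
#' belongs to pixel `(floor(x), floor(y))`); the `"area"` variant scores
#' each cell by the fraction of its disk pixels that are coated.
#'
#' @param assay a [coating_assay()].
#' @param cell_type the cell type analyzed.
#' @param membership `"centroid"` (default) or `"area"`.
#' @return An object of class `avoidance_result` with `f_cells_on`,
#'   `f_area`, `enrichment` (permutation fields `z`, `p` empty).
#' @export
occupancy_enrichment <- function(assay, cell_type = "beta",
                                 membership = c("centroid", "area")) {
  membership <- match.arg(membership)
  stopifnot(inherits(assay, "coating_assay"))
  f_area <- mean(assay$coated_mask)
  if (f_area <= 0 || f_area >= 1) {
    abort("degenerate coated mask: coated fraction must lie strictly in (0, 1)")
  }
  cells <- dplyr::filter(assay$cells, .data$cell_type == !!cell_type)
  if (nrow(cells) == 0) {
    abort(sprintf("no cells of type '%s' in the assay", cell_type))
  }
  f_cells_on <- if (membership == "centroid") {
    mean(centroid_on_mask(cells$x, cells$y, assay$coated_mask))
  } else {
    mean(vapply(seq_len(nrow(cells)), function(k) {
      disk_coated_fraction(cells$x[k], cells$y[k],
                           sqrt(cells$area[k] / pi), assay$coated_mask)
    }, numeric(1)))
  }
  structure(list(f_cells_on = f_cells_on, f_area = f_area,
                 enrichment = f_cells_on / f_area, z = NA_real_,
                 p = NA_real_, n_perm = NA_integer_, seed = NULL,
                 cell_type = cell_type, n_cells = nrow(cells),
                 membership = membership, alternative = NA_character_),
            class = "avoidance_result")
}

centroid_on_mask <- function(x, y, mask) {
  i <- floor(y) + 1L
  j <- floor(x) + 1L
  ok <- i >= 1L & i <= nrow(mask) & j >= 1L & j <= ncol(mask)
  on <- rep(FALSE, length(x))
  on[ok] <- mask[cbind(i[ok], j[ok])]
  on
}

disk_coated_fraction <- function(cx, cy, r, mask) {
  j <- max(1L, floor(cx - r) + 1L):min(ncol(mask), ceiling(cx + r) + 1L)
  i <- max(1L, floor(cy - r) + 1L):min(nrow(mask), ceiling(cy + r) + 1L)
  hit <- outer(((i - 1) - cy)^2, ((j - 1) - cx)^2, `+`) <= r^2
  if (!any(hit)) return(0)
  mean(mask[i, j, drop = FALSE][hit])
}

#' Permutation test for avoidance of a coated region
#'
#' Algorithm 2: complete spatial randomness (CSR) of cell centroids over
#' the field is the null; positions are resampled uniformly `n_perm`
#' times with the same cell count, and the observed on-coated fraction is
#' compared against the null distribution. The default alternative is
#' one-sided lower-tail (avoidance): `p = (1 + #\{null f <= observed f\})
#' / (n_perm + 1)`. The z-score is `(observed - null mean) / null sd`.
#'
#' @inheritParams occupancy_enrichment
#' @param n_perm number of CSR resamples (>= 99).
#' @param seed integer seed for the resampling.
#' @param alternative `"avoidance"` (one-sided lower tail, default) or
#'   `"two.sided"`.
#' @return A complete `avoidance_result` (enrichment + `z`, `p`).
#' @export
avoidance_permutation_test <- function(assay, cell_type = "beta",
                                       n_perm = 999, seed = NULL,
                                       alternative = c("avoidance", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("n_perm must be >= 99")
  res <- occupancy_enrichment(assay, cell_type)
  n <- res$n_cells
  h <- nrow(assay$coated_mask)
  w <- ncol(assay$coated_mask)
  with_seed(seed, {
    perm_f <- vapply(seq_len(n_perm), function(b) {
      mean(centroid_on_mask(runif(n, 0, w), runif(n, 0, h),
                            assay$coated_mask))
    }, numeric(1))
    p_lo <- (1 + sum(perm_f <= res$f_cells_on)) / (n_perm + 1)
    p_hi <- (1 + sum(perm_f >= res$f_cells_on)) / (n_perm + 1)
    res$p <- if (alternative == "avoidance") p_lo else min(1, 2 * min(p_lo, p_hi))
    null_sd <- sd(perm_f)
    res$z <- if (null_sd > 0) (res$f_cells_on - mean(perm_f)) / null_sd else NA_real_
    res$n_perm <- as.integer(n_perm)
    res$seed <- seed
    res$alternative <- alternative
    res$null_f <- perm_f
    res
  })
}

#' @export
print.avoidance_result <- function(x, ...) {
  cat(sprintf("<avoidance_result> %s cells (n = %d): f_on = %.3f, f_area = %.3f, enrichment = %.3f\n",
              x$cell_type, x$n_cells, x$f_cells_on, x$f_area, x$enrichment))
  if (!is.na(x$p)) {
    cat(sprintf("  CSR permutation (%d perms, %s): z = %.2f, p = %.4g\n",
                x$n_perm, x$alternative, x$z, x$p))
  }
  invisible(x)
}

#' @export
glance.avoidance_result <- function(x, ...) {
  tibble(cell_type = x$cell_type, n_cells = x$n_cells,
         f_cells_on = x$f_cells_on, f_area = x$f_area,
         enrichment = x$enrichment, z = x$z, p = x$p,
         n_perm = x$n_perm, membership = x$membership)
}
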