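#' Parameters for watershed cell segmentation
#'
#' @param threshold_method `"otsu"` (parameter-free, the default) or
#'   `"fixed"`.
#' @param fixed_threshold intensity threshold, used iff
#'   `threshold_method = "fixed"`.
#' @param smoothing_sigma Gaussian pre-smoothing sd in pixels (0 = none).
#' @param min_cell_area objects below this area (pixels^2) are discarded.
#' @param seg_channel name of the channel segmented (nuclear or
#'   summed-marker).
#' @param type_rules tibble with columns `cell_type`, `channel`,
#'   `min_mean`: a cell is assigned the type whose rule channel has the
#'   highest mean intensity among rules passing `min_mean`, else "other".
#' @param background_offset constant subtracted from channel means before
#'   type assignment and reporting (default 0: no background subtraction).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                smoothing_sigma = 1, min_cell_area = 20,
                                seg_channel = "nuc",
                                type_rules = default_type_rules(),
                                background_offset = 0) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("fixed_threshold is required when threshold_method = 'fixed'")
  }
  if (min_cell_area < 1) abort("min_cell_area must be >= 1")
  if (smoothing_sigma < 0) abort("smoothing_sigma must be >= 0")
  if (!is.null(type_rules)) {
    stopifnot(all(c("cell_type", "channel", "min_mean") %in% names(type_rules)))
  }
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 smoothing_sigma = smoothing_sigma,
                 min_cell_area = min_cell_area, seg_channel = seg_channel,
                 type_rules = type_rules,
                 background_offset = background_offset),
            class = "segmentation_params")
}

#' @rdname segmentation_params
#' @export
default_type_rules <- function() {
  tibble(cell_type = c("alpha", "beta", "delta"),
         channel = c("gcg", "ins", "sst"),
         min_mean = 10)
}

#' Segment a multi-channel image into cell records
#'
#' The designated channel is Gaussian-smoothed, binarized (Otsu or fixed
#' threshold), and split into instances by watershed on the distance
#' transform of the binary mask. Objects below `min_cell_area` are
#' removed. Each cell record carries the centroid (0-based pixel-center
#' coordinates), area, mean intensity in every channel, and a marker-rule
#' cell type.
#'
#' @param image named list of numeric matrices (rows = y, cols = x), one
#'   per channel.
#' @param params a [segmentation_params()].
#' @return A list with `cells` (tibble of cell records) and `labels`
#'   (integer label matrix, background 0).
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  stopifnot(is.list(image), !is.null(names(image)))
  need <- unique(c(params$seg_channel,
                   if (!is.null(params$type_rules)) params$type_rules$channel))
  missing_ch <- setdiff(need, names(image))
  if (length(missing_ch) > 0) {
    abort(paste0("image lacks channel(s): ", paste(missing_ch, collapse = ", ")))
  }
  ch <- image[[params$seg_channel]]
  dims <- dim(ch)
  empty <- list(cells = empty_cell_table(names(image)),
                labels = matrix(0L, dims[1], dims[2]))

  eb <- EBImage::Image(t(ch))
  if (params$smoothing_sigma > 0) {
    eb <- EBImage::gblur(eb, sigma = params$smoothing_sigma)
  }
  rng <- range(EBImage::imageData(eb))
  if (rng[1] == rng[2]) return(empty)
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(eb, range = rng)
  } else {
    params$fixed_threshold
  }
  bin <- eb > thr
  if (!any(bin)) return(empty)

  dm <- EBImage::distmap(bin)
  # seed separation scale ~ one expected cell radius
  ext <- max(1L, round(sqrt(params$min_cell_area / pi)))
  wl <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  labels <- t(EBImage::imageData(wl))
  storage.mode(labels) <- "integer"

  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= params$min_cell_area)
  if (length(keep) == 0) return(empty)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- relab[labels[pos]]

  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[idx]
  cx <- as.numeric(rowsum(idx[, 2] - 1, lab)) / as.numeric(rowsum(rep(1, length(lab)), lab))
  cy <- as.numeric(rowsum(idx[, 1] - 1, lab)) / as.numeric(rowsum(rep(1, length(lab)), lab))
  area <- as.numeric(table(lab))
  means <- lapply(image, function(m) {
    mu <- as.numeric(rowsum(m[idx], lab)) / area
    pmax(mu - params$background_offset, 0)
  })
  cells <- tibble(id = seq_along(keep), x = cx, y = cy, area = area,
                  cell_type = assign_types(means, params$type_rules))
  cells <- dplyr::bind_cols(
    cells, stats::setNames(as_tibble(means), paste0("mean_", names(image))))
  validate_cells(cells)
  list(cells = cells, labels = labels)
}

empty_cell_table <- function(channel_names) {
  base <- tibble(id = integer(), x = numeric(), y = numeric(),
                 area = numeric(), cell_type = character())
  for (ch in channel_names) base[[paste0("mean_", ch)]] <- numeric()
  base
}

assign_types <- function(channel_means, type_rules) {
  n <- length(channel_means[[1]])
  if (is.null(type_rules) || n == 0) return(rep("other", n))
  # per rule: the mean in its channel, NA when below that rule's floor
  scores <- vapply(seq_len(nrow(type_rules)), function(k) {
    mu <- channel_means[[type_rules$channel[k]]]
    ifelse(mu >= type_rules$min_mean[k], mu, NA_real_)
  }, numeric(n))
  scores <- matrix(scores, nrow = n)
  best <- apply(scores, 1, function(s) {
    if (all(is.na(s))) NA_integer_ else which.max(s)
  })
  ifelse(is.na(best), "other", type_rules$cell_type[best])
}

#' Area fraction of a marker mask within a region
#'
#' Morphometric marker quantification: the fraction of region pixels that
#' are marker-positive, `|marker AND region| / |region|`.
#'
#' @param marker_mask,region_mask logical matrices of identical shape.
#' @return A fraction in \[0, 1\].
#' @export
area_fraction <- function(marker_mask, region_mask) {
  stopifnot(is.logical(marker_mask), is.logical(region_mask))
  if (!identical(dim(marker_mask), dim(region_mask))) {
    abort("marker and region masks must have the same shape")
  }
  denom <- sum(region_mask)
  if (denom == 0) abort("region mask is empty: area fraction undefined")
  sum(marker_mask & region_mask) / denom
}
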