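#' @importFrom ggplot2 ggplot aes geom_point geom_path geom_step geom_hline
#'   geom_histogram geom_vline coord_equal labs theme_minimal
NULL

#' @export
autoplot.islet_pattern <- function(object, ...) {
  cells <- object$cells
  r_px <- sqrt(cells$area / pi)
  p <- ggplot(cells, aes(x = .data$x, y = .data$y, colour = .data$cell_type)) +
    geom_point(size = 2) +
    coord_equal() +
    ggplot2::scale_y_reverse() +
    labs(x = "x (px)", y = "y (px)", colour = "type") +
    theme_minimal()
  if (!is.logical(object$boundary)) {
    poly <- as.data.frame(object$boundary[c(seq_len(nrow(object$boundary)), 1), ])
    names(poly) <- c("x", "y")
    p <- p + geom_path(data = poly, aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey40")
  }
  p
}

#' @export
autoplot.islet_architecture <- function(object, ...) {
  ggplot(object$cells,
         aes(x = .data$x, y = .data$y, colour = .data$zone,
             shape = .data$cell_type)) +
    geom_point(size = 2) +
    coord_equal() +
    ggplot2::scale_y_reverse() +
    labs(x = "x (px)", y = "y (px)",
         title = sprintf("core/mantle partition (mantle depth %.1f um)",
                         object$mantle_depth)) +
    theme_minimal()
}

#' @export
autoplot.dispersion_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$t, y = .data$cdf)) +
    geom_step() +
    labs(x = "normalized pairwise distance", y = "empirical CDF",
         title = sprintf("dispersion degree = %.3f", object$dispersion_degree)) +
    theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$position, y = .data$value)) +
    geom_path() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "rank position", y = "running enrichment",
         title = sprintf("%s: ES = %.3f, NES = %.3f, p = %.3g",
                         object$set, object$es, object$nes, object$p)) +
    theme_minimal()
}

#' @export
autoplot.avoidance_result <- function(object, ...) {
  if (is.null(object$null_f)) {
    abort("autoplot needs a permutation-tested avoidance_result")
  }
  ggplot(data.frame(null_f = object$null_f), aes(x = .data$null_f)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = object$f_cells_on, colour = "red") +
    labs(x = "null fraction of cells on coated area", y = "count",
         title = sprintf("observed f_on = %.3f, p = %.3g",
                         object$f_cells_on, object$p)) +
    theme_minimal()
}
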