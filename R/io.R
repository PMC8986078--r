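#' Read and write per-cell record tables
#'
#' Cell tables round-trip through plain CSV with the column contract of
#' [cell_records()].
#'
#' @param cells a cell table.
#' @param path file path.
#' @return `read_cells_csv()` returns a validated cell tibble;
#'   `write_cells_csv()` returns `path` invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  validate_cells(cells)
  readr::write_csv(cells, path)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE)
  cells$id <- as.integer(cells$id)
  validate_cells(cells)
  cells
}

#' Read an activity/expression matrix from TSV
#'
#' @param path a TSV file with a `cell` column, an optional `group`
#'   column, and one numeric column per feature. With
#'   `orientation = "features_in_rows"`, rows are features and columns
#'   cells (first column = feature name) and the table is transposed.
#' @param orientation `"cells_in_rows"` (default) or
#'   `"features_in_rows"`.
#' @return A tibble in cells-in-rows orientation.
#' @export
read_activity_tsv <- function(path, orientation = c("cells_in_rows",
                                                    "features_in_rows")) {
  orientation <- match.arg(orientation)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (orientation == "features_in_rows") {
    feats <- tab[[1]]
    vals <- t(as.matrix(tab[, -1]))
    out <- tibble(cell = colnames(tab)[-1])
    out <- dplyr::bind_cols(out, stats::setNames(as_tibble(vals), feats))
    tab <- out
  }
  if (anyNA(tab)) abort("activity matrix contains missing values")
  tab
}
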