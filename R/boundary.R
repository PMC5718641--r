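#' Pectoral boundary curve
#'
#' One horizontal coordinate per image row: the right-most muscle column of
#' that row (left-MLO convention, muscle anchored at the chest wall).
#' Coordinates are stored 1-based like all R-level indices; file exports
#' ([write_boundary_csv()]) are 0-based.
#'
#' @param row integer vector of row indices (1-based).
#' @param col integer vector of column indices (1-based), same length.
#' @return A data.frame of class `boundary_curve` with columns `row`,
#'   `col`.
#' @export
boundary_curve <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (length(row) != length(col)) stop("`row` and `col` lengths differ")
  if (!length(row)) stop("a boundary curve needs at least one row")
  if (anyNA(row) || anyNA(col)) stop("NA coordinates")
  if (any(row < 1L) || any(col < 1L)) stop("coordinates must be >= 1")
  if (anyDuplicated(row)) stop("one coordinate per row")
  structure(data.frame(row = row, col = col),
            class = c("boundary_curve", "data.frame"))
}

#' Boundary curve of a binary mask
#'
#' Right-most `TRUE` column per row intersecting the mask.
#'
#' @param mask logical matrix.
#' @return A [boundary_curve()].
#' @export
boundary_from_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix")
  }
  rows <- which(apply(mask, 1L, any))
  if (!length(rows)) stop("empty mask")
  cols <- vapply(rows, function(r) max(which(mask[r, ])), integer(1))
  boundary_curve(rows, cols)
}

#' Rasterize a boundary curve to a point set
#'
#' @param b a [boundary_curve()].
#' @return Two-column integer matrix (row, col), one point per row of the
#'   curve; the form consumed by [hausdorff_distance()].
#' @export
boundary_points <- function(b) {
  stopifnot(inherits(b, "boundary_curve"))
  cbind(row = b$row, col = b$col)
}

#' Write a boundary curve as CSV (0-based coordinates)
#'
#' @param b a [boundary_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(b, path) {
  stopifnot(inherits(b, "boundary_curve"))
  utils::write.csv(data.frame(row = b$row - 1L, col = b$col - 1L),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a boundary curve from CSV (0-based coordinates)
#'
#' @param path CSV with columns `row`, `col`, 0-based.
#' @return A [boundary_curve()].
#' @export
read_boundary_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(d))) {
    stop("boundary CSV needs `row` and `col` columns")
  }
  boundary_curve(d$row + 1L, d$col + 1L)
}
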