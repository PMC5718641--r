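#' Area-normalized false positive and false negative boundary errors
#'
#' Row-wise comparison of a predicted pectoral boundary against ground
#' truth for a left-MLO view: in each row the signed column difference
#' between the two boundaries is split into overshoot (FP) and undershoot
#' (FN) and normalized by the ground-truth muscle area, so
#' `FP = (1/A) * sum_i max(0, Balg(i) - Bgro(i))` and symmetrically for
#' FN. Rows where only one curve is defined claim no muscle on the other
#' side (column 0 in the 0-based convention), so over- or under-shooting
#' the muscle's length is charged in full.
#'
#' @param pred,truth [boundary_curve()] objects.
#' @param truth_area ground-truth muscle area in pixels (`A`); defaults to
#'   the area enclosed by `truth` (sum of its per-row widths).
#' @return Named list with `fp` and `fn` (fractions of `A`).
#' @export
fp_fn_area_normalized <- function(pred, truth,
                                  truth_area = sum(truth$col)) {
  stopifnot(inherits(pred, "boundary_curve"),
            inherits(truth, "boundary_curve"))
  if (!is.numeric(truth_area) || truth_area < 1) {
    stop("`truth_area` must be >= 1")
  }
  rows <- sort(union(pred$row, truth$row))
  # 0-based columns; undefined rows claim column 0
  b_alg <- (pred$col - 1L)[match(rows, pred$row)]
  b_gro <- (truth$col - 1L)[match(rows, truth$row)]
  b_alg[is.na(b_alg)] <- 0L
  b_gro[is.na(b_gro)] <- 0L
  d <- b_alg - b_gro
  list(fp = sum(pmax(0L, d)) / truth_area,
       fn = sum(pmax(0L, -d)) / truth_area)
}

#' Hausdorff distance between two boundary pixel sets
#'
#' `H(A,B) = max(h(A,B), h(B,A))` with `h` the directed distance
#' `max_p min_q ||p - q||` over Euclidean point distances. Inputs are the
#' rasterized boundary point sets, not filled regions.
#'
#' @param a,b two-column matrices of (row, col) pixel coordinates, or
#'   [boundary_curve()] objects.
#' @param pixel_mm physical pixel spacing used for the millimetre value.
#' @return Named list with `hausdorff_px` and `hausdorff_mm`.
#' @export
hausdorff_distance <- function(a, b, pixel_mm = 1) {
  a <- as_point_matrix(a); b <- as_point_matrix(b)
  if (!nrow(a) || !nrow(b)) stop("point sets must be non-empty")
  if (!is.numeric(pixel_mm) || pixel_mm <= 0) {
    stop("`pixel_mm` must be positive")
  }
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  h_ab <- sqrt(max(apply(d2, 1L, min)))
  h_ba <- sqrt(max(apply(d2, 2L, min)))
  hpx <- max(h_ab, h_ba)
  list(hausdorff_px = hpx, hausdorff_mm = hpx * pixel_mm)
}

as_point_matrix <- function(x) {
  if (inherits(x, "boundary_curve")) return(boundary_points(x))
  if (!is.matrix(x) || ncol(x) != 2L) {
    stop("point set must be a two-column (row, col) matrix")
  }
  x
}

#' Evaluate a prediction against ground truth
#'
#' Bundles [fp_fn_area_normalized()] and [hausdorff_distance()] into one
#' per-image evaluation record.
#'
#' @inheritParams fp_fn_area_normalized
#' @param pixel_mm pixel spacing for the Hausdorff millimetre value.
#' @return An object of class `evaluation_result`: `fp`, `fn`,
#'   `hausdorff_px`, `hausdorff_mm`.
#' @export
evaluate_boundary <- function(pred, truth, truth_area = sum(truth$col),
                              pixel_mm = 1) {
  e <- fp_fn_area_normalized(pred, truth, truth_area)
  h <- hausdorff_distance(pred, truth, pixel_mm)
  structure(c(e, h), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> FP %.4f  FN %.4f  Hausdorff %.2f px (%.2f mm)\n",
              x$fp, x$fn, x$hausdorff_px, x$hausdorff_mm))
  invisible(x)
}

#' Batch evaluation summary
#'
#' Arithmetic means of the per-image error terms plus mean and standard
#' deviation of the Hausdorff distance, and counts of images per
#' error-range bin. The six mutually exclusive bins are the conventional
#' reporting scheme: both errors below 0.05; the smaller below 0.05 with
#' the larger in [0.05, 0.10); the smaller below 0.05 with the larger at
#' or above 0.10; both in [0.05, 0.10); the smaller in [0.05, 0.10) with
#' the larger at or above 0.10; both at or above 0.10.
#'
#' @param per_image list of `evaluation_result` objects.
#' @return An object of class `batch_summary`: `n`, `fp_mean`, `fn_mean`,
#'   `hausdorff_mean`, `hausdorff_sd` (`NA` for n = 1), `bins` (named
#'   integer vector of length 6 summing to `n`).
#' @export
batch_means <- function(per_image) {
  if (!is.list(per_image) || !length(per_image)) {
    stop("`per_image` must be a non-empty list")
  }
  ok <- vapply(per_image, inherits, logical(1), "evaluation_result")
  if (!all(ok)) stop("all elements must be evaluation_result objects")
  fp <- vapply(per_image, `[[`, numeric(1), "fp")
  fn <- vapply(per_image, `[[`, numeric(1), "fn")
  hpx <- vapply(per_image, `[[`, numeric(1), "hausdorff_px")
  hmm <- vapply(per_image, `[[`, numeric(1), "hausdorff_mm")
  bins <- vapply(seq_along(fp), function(i) error_bin(fp[i], fn[i]),
                 integer(1))
  bin_counts <- tabulate(bins, nbins = 6L)
  names(bin_counts) <- c(
    "FP<0.05 & FN<0.05",
    "min<0.05 & 0.05<=max<0.10",
    "min<0.05 & max>=0.10",
    "0.05<=FP<0.10 & 0.05<=FN<0.10",
    "0.05<=min<0.10 & max>=0.10",
    "FP>=0.10 & FN>=0.10")
  structure(list(n = length(fp),
                 fp_mean = mean(fp), fn_mean = mean(fn),
                 hausdorff_mean = mean(hpx),
                 hausdorff_sd = stats::sd(hpx),
                 hausdorff_mm_mean = mean(hmm),
                 bins = bin_counts),
            class = "batch_summary")
}

error_bin <- function(fp, fn) {
  m <- min(fp, fn); M <- max(fp, fn)
  if (m < 0.05 && M < 0.05) return(1L)
  if (m < 0.05 && M < 0.10) return(2L)
  if (m < 0.05) return(3L)
  if (m < 0.10 && M < 0.10) return(4L)
  if (m < 0.10) return(5L)
  6L
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> n = %d\n", x$n))
  cat(sprintf("  FP mean %.4f   FN mean %.4f\n", x$fp_mean, x$fn_mean))
  cat(sprintf("  Hausdorff mean %.2f px (sd %.2f)\n",
              x$hausdorff_mean, x$hausdorff_sd))
  for (i in seq_along(x$bins)) {
    cat(sprintf("  %-30s %d\n", names(x$bins)[i], x$bins[i]))
  }
  invisible(x)
}
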