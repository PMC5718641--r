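#' Normalise a mammogram to left-MLO orientation
#'
#' The whole pipeline is written for left-MLO views (pectoral muscle in the
#' top-left corner); a right-MLO mammogram is mirrored horizontally before
#' processing and the result mirrored back afterwards. With `side = "auto"`
#' laterality is inferred by comparing the summed intensity of the left and
#' right image halves: the breast is the bright half.
#'
#' @param img a [gray_image()].
#' @param side `"left"`, `"right"` or `"auto"`.
#' @return A list of class `orientation_result` with elements `image`
#'   (left-MLO oriented [gray_image()]) and `was_flipped` (logical).
#' @export
orient_to_left_mlo <- function(img, side = c("auto", "left", "right")) {
  assert_gray_image(img)
  side <- match.arg(side)
  flip <- switch(side,
    left = FALSE,
    right = TRUE,
    auto = {
      half <- img$width_px %/% 2L
      left_sum <- sum(as.numeric(img$pixels[, seq_len(half)]))
      right_sum <- sum(as.numeric(
        img$pixels[, (img$width_px - half + 1L):img$width_px]))
      right_sum > left_sum
    })
  out <- if (flip) flip_horizontal(img) else img
  structure(list(image = out, was_flipped = flip),
            class = "orientation_result")
}

#' Mirror an image horizontally
#'
#' Column-reversal; applying it twice restores the original exactly.
#'
#' @param img a [gray_image()].
#' @return The mirrored [gray_image()].
#' @export
flip_horizontal <- function(img) {
  assert_gray_image(img)
  gray_image(img$pixels[, rev(seq_len(img$width_px)), drop = FALSE],
             pixel_mm = img$pixel_mm)
}

#' Resize a mammogram to the working resolution
#'
#' Downsampling uses block (area) averaging so that constant regions stay
#' constant and no aliasing ridges are introduced; upsampling uses
#' nearest-neighbour replication. The default working size is 256, matching
#' a 1024x1024 scan at 200 microns reduced to 0.8 mm/px. `pixel_mm` is
#' rescaled so the physical extent of the image is preserved.
#'
#' @param img a [gray_image()].
#' @param target output side length in pixels (the output is
#'   `target` x `target`).
#' @return A [gray_image()] of size `target` x `target`.
#' @export
resize_to_working <- function(img, target = 256L) {
  assert_gray_image(img)
  target <- as.integer(target)
  if (is.na(target) || target < 3L) stop("`target` must be >= 3")
  px <- resize_axis(resize_axis(img$pixels, target), target, cols = TRUE)
  px <- round_half_up(px)
  gray_image(px, pixel_mm = img$pixel_mm * img$height_px / target)
}

# Resample one axis: area-average bins when shrinking, nearest neighbour
# when enlarging. Operates on rows unless cols = TRUE.
resize_axis <- function(px, target, cols = FALSE) {
  if (cols) return(t(resize_axis(t(px), target)))
  n <- nrow(px)
  if (n == target) return(px)
  if (target < n) {
    bin <- pmin(as.integer(floor((seq_len(n) - 1L) * target / n)) + 1L, target)
    rs <- rowsum(px, group = bin)
    cnt <- tabulate(bin, nbins = target)
    rs / cnt
  } else {
    src <- as.integer(floor((seq_len(target) - 1L) * n / target)) + 1L
    px[src, , drop = FALSE]
  }
}

round_half_up <- function(x) floor(x + 0.5)

#' Remove the unexposed left border strip
#'
#' MIAS-era films carry an unexposed (near-zero) strip along the chest-wall
#' edge of the image. Leading columns whose intensities are uniformly at or
#' below `background_threshold` are removed so the top-left pixel of the
#' remaining image lies inside the pectoral muscle.
#'
#' @param img a left-MLO oriented [gray_image()].
#' @param background_threshold intensity at or below which a pixel counts
#'   as background (default 10 on the 8-bit scale).
#' @return A list of class `roi_image`: `image` ([gray_image()]),
#'   `offset_row`, `offset_col` (0-based offsets of the sub-image inside
#'   its source).
#' @export
strip_unexposed_border <- function(img, background_threshold = 10L) {
  assert_gray_image(img)
  bg <- col_is_background(img$pixels, background_threshold)
  if (all(bg)) stop("no breast content: whole image at or below threshold")
  first_fg <- which(!bg)[1L]
  px <- img$pixels[, first_fg:img$width_px, drop = FALSE]
  if (ncol(px) < 3L) stop("image too narrow after border stripping")
  roi_image(gray_image(px, pixel_mm = img$pixel_mm),
            offset_row = 0L, offset_col = first_fg - 1L)
}

col_is_background <- function(px, thr) {
  apply(px <= thr, 2L, all)
}

roi_image <- function(image, offset_row, offset_col) {
  structure(list(image = image,
                 offset_row = as.integer(offset_row),
                 offset_col = as.integer(offset_col)),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %d x %d px at offset (row %d, col %d), %.4g mm/px\n",
              x$image$height_px, x$image$width_px,
              x$offset_row, x$offset_col, x$image$pixel_mm))
  invisible(x)
}

#' Estimate the skin-air boundary column in the upper rows
#'
#' Scans the first `n_rows` rows and returns the right-most column (1-based)
#' holding an above-threshold pixel: the column bounding the region of
#' interest on the right so it encloses the whole pectoral muscle. The
#' default `n_rows` is `ceiling(height/8)` (32 rows at working size).
#'
#' @param img a left-MLO oriented [gray_image()] (border already stripped).
#' @param n_rows number of top rows to scan.
#' @param background_threshold see [strip_unexposed_border()].
#' @return 1-based column index of the skin-air boundary.
#' @export
estimate_skin_air_column <- function(img,
                                     n_rows = ceiling(img$height_px / 8),
                                     background_threshold = 10L) {
  assert_gray_image(img)
  n_rows <- as.integer(n_rows)
  if (is.na(n_rows) || n_rows < 1L) stop("`n_rows` must be >= 1")
  if (n_rows > img$height_px) stop("`n_rows` exceeds image height")
  top <- img$pixels[seq_len(n_rows), , drop = FALSE]
  fg_cols <- which(apply(top > background_threshold, 2L, any))
  if (!length(fg_cols)) {
    stop("no above-threshold pixel in the first ", n_rows, " rows")
  }
  max(fg_cols)
}

#' Extract the region of interest containing the pectoral muscle
#'
#' Returns the axis-aligned rectangle spanning all rows and columns
#' 1..`skin_air_col` — the region reaching from the chest wall to the
#' skin-air boundary estimated in the upper rows, which encloses the whole
#' muscle in an MLO view.
#'
#' @param img a left-MLO oriented [gray_image()].
#' @param skin_air_col 1-based right bound, e.g. from
#'   [estimate_skin_air_column()].
#' @return A `roi_image` (see [strip_unexposed_border()]).
#' @export
extract_roi <- function(img, skin_air_col) {
  assert_gray_image(img)
  skin_air_col <- as.integer(skin_air_col)
  if (is.na(skin_air_col) || skin_air_col < 1L ||
      skin_air_col > img$width_px) {
    stop("`skin_air_col` outside the image")
  }
  if (skin_air_col < 3L) stop("ROI narrower than 3 columns")
  px <- img$pixels[, seq_len(skin_air_col), drop = FALSE]
  roi_image(gray_image(px, pixel_mm = img$pixel_mm),
            offset_row = 0L, offset_col = 0L)
}
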