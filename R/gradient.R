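#' Sobel gradient magnitude
#'
#' Convolves the region of interest with the two 3x3 Sobel masks
#' (horizontal mask `[-1 0 1; -2 0 2; -1 0 1]` and its transpose) and
#' combines them as `G = sqrt(Gx^2 + Gy^2)`. Borders are handled by
#' replicate-edge padding so the image frame does not generate spurious
#' gradient ridges.
#'
#' @param roi a [gray_image()] of at least 3x3.
#' @return A `gradient_image`: list with `pixels` (non-negative numeric
#'   matrix), `pixel_mm`, and `quantized = FALSE`.
#' @export
sobel_gradient_magnitude <- function(roi) {
  assert_gray_image(roi)
  gxy <- sobel_components(roi$pixels)
  g <- sqrt(gxy$gx^2 + gxy$gy^2)
  gradient_image(g, roi$pixel_mm, quantized = FALSE)
}

#' Sobel gradient direction
#'
#' `atan2(Gy, Gx)` per pixel, in radians. The direction is a diagnostic
#' output only — nothing downstream consumes it. Pixels with zero gradient
#' are assigned angle 0 by convention.
#'
#' @param roi a [gray_image()].
#' @return Numeric matrix of angles in `(-pi, pi]`.
#' @export
gradient_direction <- function(roi) {
  assert_gray_image(roi)
  gxy <- sobel_components(roi$pixels)
  ang <- atan2(gxy$gy, gxy$gx)
  ang[gxy$gx == 0 & gxy$gy == 0] <- 0
  ang
}

sobel_components <- function(px) {
  p <- pad_replicate(px)
  # correlation with the masks; shifted copies of the padded image
  s <- function(dr, dc) {
    p[(2L + dr):(nrow(px) + 1L + dr), (2L + dc):(ncol(px) + 1L + dc),
      drop = FALSE]
  }
  gx <- -s(-1, -1) + s(-1, 1) - 2 * s(0, -1) + 2 * s(0, 1) -
    s(1, -1) + s(1, 1)
  gy <- -s(-1, -1) - 2 * s(-1, 0) - s(-1, 1) +
    s(1, -1) + 2 * s(1, 0) + s(1, 1)
  list(gx = gx, gy = gy)
}

pad_replicate <- function(px) {
  px <- px[c(1L, seq_len(nrow(px)), nrow(px)), , drop = FALSE]
  px[, c(1L, seq_len(ncol(px)), ncol(px)), drop = FALSE]
}

gradient_image <- function(pixels, pixel_mm, quantized) {
  stopifnot(is.matrix(pixels), all(pixels >= 0))
  structure(list(pixels = pixels, pixel_mm = pixel_mm,
                 quantized = quantized),
            class = "gradient_image")
}

#' @export
print.gradient_image <- function(x, ...) {
  cat(sprintf("<gradient_image> %d x %d px, range [%.3g, %.3g]%s\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (x$quantized) ", quantized" else ""))
  invisible(x)
}

#' 3x3 mean filter with integer quantization
#'
#' Smooths the gradient with a 3x3 box average (replicate-edge padding) to
#' suppress irrelevant regional minima before flooding, then rounds
#' half-up to integers: the immersion recursion iterates over discrete
#' levels, so its input must be a discrete altitude map. Integer rounding
#' bounds the flooding at 1444 levels (max Sobel magnitude on 8-bit input
#' is sqrt(2) * 1020 ~ 1442.5).
#'
#' @param g a `gradient_image` (or any non-negative matrix).
#' @return A quantized `gradient_image` of the same size.
#' @export
mean_filter_3x3 <- function(g) {
  px <- if (inherits(g, "gradient_image")) g$pixels else g
  pmm <- if (inherits(g, "gradient_image")) g$pixel_mm else NA_real_
  if (!is.matrix(px) || nrow(px) < 3L || ncol(px) < 3L) {
    stop("mean filter needs a matrix of at least 3x3")
  }
  p <- pad_replicate(px)
  s <- function(dr, dc) {
    p[(2L + dr):(nrow(px) + 1L + dr), (2L + dc):(ncol(px) + 1L + dc),
      drop = FALSE]
  }
  m <- (s(-1, -1) + s(-1, 0) + s(-1, 1) +
        s(0, -1) + s(0, 0) + s(0, 1) +
        s(1, -1) + s(1, 0) + s(1, 1)) / 9
  q <- round_half_up(m)
  storage.mode(q) <- "integer"
  gradient_image(q, pmm, quantized = TRUE)
}
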