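#' Grayscale mammogram image
#'
#' Light-weight container for an 8-bit grayscale raster together with its
#' physical pixel spacing. All pectoshed operations consume and produce
#' `gray_image` objects. Pixels are stored as an integer-valued matrix in
#' row/column order; indices at the R level are 1-based, while every file
#' interface (CSV/JSON) uses 0-based coordinates and says so.
#'
#' @param pixels numeric or integer matrix with values in `[0, 255]`. At
#'   least 3x3 (the minimum on which a 3x3 convolution is defined).
#' @param pixel_mm physical edge length of one pixel in millimetres
#'   (0.2 mm for a full-resolution 1024x1024 MIAS scan digitised at
#'   200 microns; 0.8 mm at the 256x256 working size).
#' @return An object of class `gray_image` with elements `pixels`,
#'   `height_px`, `width_px`, `pixel_mm`.
#' @examples
#' img <- gray_image(matrix(0L, 8, 8), pixel_mm = 0.2)
#' img$height_px
#' @export
gray_image <- function(pixels, pixel_mm = 0.2) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3x3, got ",
         nrow(pixels), "x", ncol(pixels))
  }
  if (anyNA(pixels)) stop("`pixels` contains NA")
  if (any(pixels < 0) || any(pixels > 255)) {
    stop("intensities must lie in [0, 255]")
  }
  if (!is.numeric(pixel_mm) || length(pixel_mm) != 1L || pixel_mm <= 0) {
    stop("`pixel_mm` must be a single positive number")
  }
  storage.mode(pixels) <- "integer"
  dimnames(pixels) <- NULL
  structure(
    list(pixels = pixels,
         height_px = nrow(pixels),
         width_px = ncol(pixels),
         pixel_mm = as.numeric(pixel_mm)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g mm/px, intensities [%d, %d]\n",
              x$height_px, x$width_px, x$pixel_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(x, arg = deparse(substitute(x))) {
  if (!is_gray_image(x)) stop("`", arg, "` must be a gray_image")
  invisible(x)
}

#' Read a PGM mammogram
#'
#' Reads an 8-bit single-channel PGM file, either plain (`P2`) or raw
#' (`P5`). This is the MIAS-era format; no other raster formats are
#' supported by the package.
#'
#' @param path path to a `.pgm` file.
#' @param pixel_mm physical pixel spacing to attach (not stored in PGM).
#' @return A [gray_image()].
#' @seealso [write_pgm()]
#' @export
load_mammogram <- function(path, pixel_mm = 0.2) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path")
  }
  if (!file.exists(path)) stop("cannot read mammogram: no such file: ", path)
  px <- read_pgm_pixels(path)
  if (nrow(px) < 3L || ncol(px) < 3L) {
    stop("image in ", path, " is below the 3x3 minimum size")
  }
  px[px > 255L] <- 255L
  px[px < 0L] <- 0L
  gray_image(px, pixel_mm = pixel_mm)
}

# Parse P2/P5 PGM into an integer matrix (rows x cols).
read_pgm_pixels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("unsupported raster format in ", path,
         " (expected PGM magic P2 or P5, got '", magic, "')")
  }
  # header tokens: width, height, maxval; '#' comments run to end of line
  toks <- integer(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(toks) < 3L) {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("truncated PGM header in ", path)
    ch <- rawToChar(ch)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") {
      in_comment <- TRUE
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        toks <- c(toks, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop("invalid PGM dimensions in ", path)
  }
  if (is.na(maxval) || maxval < 1L || maxval > 255L) {
    stop("only 8-bit PGM supported (maxval ", maxval, ") in ", path)
  }
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM pixel data in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an image or mask as plain PGM (P2)
#'
#' @param x a [gray_image()], or an integer/logical matrix (logical is
#'   written as 0/255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path) {
  if (is_gray_image(x)) x <- x$pixels
  if (is.logical(x)) x <- ifelse(x, 255L, 0L)
  if (!is.matrix(x)) stop("`x` must be a matrix or gray_image")
  storage.mode(x) <- "integer"
  if (any(x < 0L) || any(x > 255L)) stop("pixel values outside [0,255]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), "255"), con)
  writeLines(apply(x, 1L, paste, collapse = " "), con)
  invisible(path)
}
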