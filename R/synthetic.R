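#' Specification of a synthetic left-MLO phantom
#'
#' A phantom states the world the pipeline is tested in: a bright, roughly
#' triangular pectoral region anchored at the top-left corner and bounded
#' by a straight or curved edge whose width decreases from top to bottom;
#' darker breast tissue with Gaussian texture noise; a curved skin-air
#' boundary with dark air beyond it; and an unexposed near-zero strip at
#' the left film edge. The strip overlays the muscle's left margin:
#' ground-truth rows end where the total muscle width no longer exceeds
#' the strip width, so the visible muscle and the recorded truth stay
#' consistent.
#'
#' @param size working side length in pixels.
#' @param boundary_kind `"straight"` (edge at `angle_deg` to the image top
#'   edge; at 45 degrees the width shrinks by one column per row) or
#'   `"quadratic"` (width decays quadratically to zero).
#' @param angle_deg pectoral edge angle for the straight case, within
#'   30-70 degrees.
#' @param top_width_frac muscle width on the top row as a fraction of
#'   `size`.
#' @param pectoral_mean,tissue_mean mean intensities of muscle and breast
#'   tissue; their difference is the edge contrast (default 160 - 120 =
#'   40, a visible but mammographically low-contrast edge).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (clamped to `[0, 255]` after adding).
#' @param n_dense_blobs number of bright confounder blobs placed in the
#'   tissue near the pectoral edge (dense-tissue mimics).
#' @param unexposed_cols width of the left unexposed strip.
#' @param rng_seed integer seed; identical specs generate identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256L,
                         boundary_kind = c("straight", "quadratic"),
                         angle_deg = 50,
                         top_width_frac = 0.45,
                         pectoral_mean = 160,
                         tissue_mean = 120,
                         noise_sd = 5,
                         n_dense_blobs = 0L,
                         unexposed_cols = 8L,
                         rng_seed = 1L) {
  boundary_kind <- match.arg(boundary_kind)
  size <- as.integer(size)
  if (size < 32L) stop("`size` must be >= 32")
  if (angle_deg < 30 || angle_deg > 70) {
    stop("`angle_deg` must lie in [30, 70]")
  }
  if (tissue_mean <= 0 || pectoral_mean > 255 ||
      pectoral_mean <= tissue_mean) {
    stop("need 0 < tissue_mean < pectoral_mean <= 255")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (top_width_frac <= 0 || top_width_frac >= 0.8) {
    stop("`top_width_frac` must lie in (0, 0.8)")
  }
  structure(list(size = size, boundary_kind = boundary_kind,
                 angle_deg = angle_deg, top_width_frac = top_width_frac,
                 pectoral_mean = pectoral_mean, tissue_mean = tissue_mean,
                 noise_sd = noise_sd,
                 n_dense_blobs = as.integer(n_dense_blobs),
                 unexposed_cols = as.integer(unexposed_cols),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# per-row muscle width (in pixels, measured from column 1) and the
# skin-air right limit for each row
phantom_geometry <- function(spec) {
  s <- spec$size
  r0 <- seq_len(s) - 1L                      # 0-based rows
  w0 <- round(spec$top_width_frac * s)
  width <- switch(spec$boundary_kind,
    straight = w0 - r0 / tan(spec$angle_deg * pi / 180),
    quadratic = {
      stop_row <- 0.85 * s                   # row where the width reaches 0
      w0 * pmax(0, 1 - r0 / stop_row)^2
    })
  width <- pmax(0L, as.integer(round(width)))
  skin <- as.integer(round((s - 1) * (0.92 - 0.25 * (r0 / (s - 1))^2))) + 1L
  list(width = width, skin_air_col = pmin(skin, s))
}

#' Generate a synthetic left-MLO phantom with exact ground truth
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom`: `image` ([gray_image()], working
#'   scale at 0.8 mm/px), `truth_mask` (logical matrix), `truth_boundary`
#'   ([boundary_curve()], right-most muscle column per row),
#'   `truth_area` (pixels), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  geo <- phantom_geometry(spec)
  width <- geo$width
  # ground truth stops where the muscle would be fully hidden by the strip
  truth_rows <- which(width > spec$unexposed_cols)
  if (!length(truth_rows)) stop("degenerate phantom: muscle never visible")
  truth_mask <- matrix(FALSE, s, s)
  for (r in truth_rows) truth_mask[r, seq_len(width[r])] <- TRUE

  img <- withr::with_seed(spec$rng_seed, {
    # noise is drawn first so that the RNG stream consumed by blob
    # placement does not change it: with the same seed, phantoms with and
    # without blobs differ only within the blob footprints
    noise <- matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
    px <- matrix(spec$tissue_mean, s, s)
    for (r in seq_len(s)) {
      if (width[r] > 0L) px[r, seq_len(width[r])] <- spec$pectoral_mean
    }
    if (spec$n_dense_blobs > 0L) {
      px <- add_dense_blobs(px, spec, width)
    }
    px <- px + noise
    # air beyond the skin-air curve, then the unexposed strip
    for (r in seq_len(s)) {
      if (geo$skin_air_col[r] < s) px[r, (geo$skin_air_col[r] + 1L):s] <- 0
    }
    if (spec$unexposed_cols > 0L) px[, seq_len(spec$unexposed_cols)] <- 0
    round_half_up(pmax(pmin(px, 255), 0))
  })

  structure(list(image = gray_image(img, pixel_mm = 0.8),
                 truth_mask = truth_mask,
                 truth_boundary = boundary_curve(truth_rows,
                                                 width[truth_rows]),
                 truth_area = sum(width[truth_rows]),
                 spec = spec),
            class = "phantom")
}

# bright circular blobs in the tissue close to the pectoral edge,
# mimicking dense tissue abutting the muscle (uses the active RNG)
add_dense_blobs <- function(px, spec, width) {
  s <- spec$size
  rows_vis <- which(width > spec$unexposed_cols)
  for (i in seq_len(spec$n_dense_blobs)) {
    r0 <- sample(rows_vis, 1L)
    rad <- sample(4:8, 1L)
    c0 <- width[r0] + rad + sample(2:10, 1L)
    if (c0 + rad > s) next
    rr <- pmax(1L, r0 - rad):pmin(s, r0 + rad)
    cc <- pmax(1L, c0 - rad):pmin(s, c0 + rad)
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    patch <- px[rr, cc, drop = FALSE]
    patch[d2 <= rad^2] <- spec$pectoral_mean
    px[rr, cc] <- patch
  }
  px
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d x %d px, %s edge, contrast %g, noise sd %g, area %d px\n",
    x$spec$size, x$spec$size, x$spec$boundary_kind,
    x$spec$pectoral_mean - x$spec$tissue_mean, x$spec$noise_sd,
    x$truth_area))
  invisible(x)
}

#' Generate a reproducible batch of phantoms
#'
#' Per-instance seeds are derived deterministically from `master_seed`;
#' the edge angle is jittered uniformly within `angle_range` and the
#' contrast within `contrast_jitter` of the base value (0 by default, so
#' default batches share the base contrast).
#'
#' @param n number of phantoms.
#' @param base_spec a [phantom_spec()] supplying everything not jittered.
#' @param master_seed integer seed for the batch.
#' @param angle_range range the per-instance edge angle is drawn from.
#' @param contrast_jitter half-width of the uniform contrast jitter.
#' @return List of `phantom` objects.
#' @export
phantom_batch <- function(n, base_spec = phantom_spec(), master_seed = 7L,
                          angle_range = c(40, 60), contrast_jitter = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  stopifnot(inherits(base_spec, "phantom_spec"))
  lapply(seq_len(n), function(i) {
    # an independent stream per instance, so that instance i of a batch
    # does not depend on n (below 2^31 by construction)
    instance_seed <- as.integer(
      (as.double(master_seed) * 7919 + i * 104729) %% 2147483629)
    draws <- withr::with_seed(instance_seed, {
      list(seed = sample.int(2147483646L, 1L),
           angle = stats::runif(1, angle_range[1], angle_range[2]),
           dcontrast = stats::runif(1, -contrast_jitter, contrast_jitter))
    })
    sp <- base_spec
    sp$rng_seed <- draws$seed
    sp$angle_deg <- min(70, max(30, draws$angle))
    contrast <- base_spec$pectoral_mean - base_spec$tissue_mean +
      draws$dcontrast
    sp$tissue_mean <- sp$pectoral_mean - contrast
    if (sp$tissue_mean <= 0) stop("contrast jitter produced tissue_mean <= 0")
    generate_phantom(sp)
  })
}
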