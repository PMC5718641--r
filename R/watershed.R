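#' Label image: catchment basins plus watershed pixels
#'
#' Output container of the watershed transform. `labels` holds one integer
#' per pixel: basin labels `1..n_basins`, with `0` reserved for watershed
#' (dam) pixels. Basin labels are allocated in raster-scan order of each
#' basin's first pixel, so the labelling is deterministic.
#'
#' @param labels integer matrix of labels (0 = watershed).
#' @param n_basins number of catchment basins.
#' @param ... further fields stored on the object (diagnostics).
#' @return An object of class `label_image`.
#' @export
label_image <- function(labels, n_basins = max(labels), ...) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be >= 0")
  n_basins <- as.integer(n_basins)
  if (n_basins < 1L) stop("a label image needs at least one basin")
  structure(list(labels = labels, n_basins = n_basins, ...),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d px, %d basins, %d watershed pixels\n",
              nrow(x$labels), ncol(x$labels), x$n_basins,
              sum(x$labels == 0L)))
  invisible(x)
}

as_altitude_matrix <- function(g) {
  px <- if (inherits(g, "gradient_image")) g$pixels else g
  if (inherits(g, "gradient_image") && !isTRUE(g$quantized)) {
    stop("altitudes must be quantized; apply mean_filter_3x3() first")
  }
  if (!is.matrix(px) || !is.numeric(px)) stop("altitudes must be a matrix")
  if (any(px != floor(px))) stop("altitudes must be integer-valued")
  storage.mode(px) <- "integer"
  px
}

#' Immersion-based watershed transform
#'
#' Floods the quantized altitude map level by level: basins grow from the
#' regional minima; at each gray level the newly submerged pixels join the
#' geodesic influence zone of the nearest basin (8-connected unit-cost
#' paths within the threshold set), pixels equidistant between two basins
#' become dam (watershed) pixels, and newly emerging minima seed fresh
#' basins. Watershed pixels carry label 0 in the result.
#'
#' @param g a quantized `gradient_image` (see [mean_filter_3x3()]) or an
#'   integer matrix of altitudes.
#' @return A [label_image()] with extra diagnostic fields `levels` (the
#'   distinct altitudes flooded) and `assigned_per_level` (cumulative count
#'   of basin pixels after each level; non-decreasing by construction of
#'   the recursion).
#' @export
immersion_watershed <- function(g) {
  f <- as_altitude_matrix(g)
  res <- .immersion_watershed_cpp(f)
  label_image(res$labels, n_basins = res$n_basins,
              levels = res$levels,
              assigned_per_level = res$assigned_per_level)
}

#' Regional minima of an altitude map
#'
#' A regional minimum is an 8-connected constant-altitude plateau all of
#' whose outside neighbours are strictly higher. Each minimum is one
#' labelled component in the result; non-minimum pixels are 0.
#'
#' @inheritParams immersion_watershed
#' @return A [label_image()] whose basins are the minima components.
#' @export
find_regional_minima <- function(g) {
  f <- as_altitude_matrix(g)
  nr <- nrow(f); nc <- ncol(f)
  # a plateau is not a minimum iff some pixel of it has a lower neighbour;
  # mark pixels with a strictly lower 8-neighbour, then discard any plateau
  # component containing such a pixel
  lower <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rs <- seq_len(nr); cs <- seq_len(nc)
    rd <- rs + dr; cd <- cs + dc
    ok_r <- rd >= 1L & rd <= nr; ok_c <- cd >= 1L & cd <= nc
    lower[rs[ok_r], cs[ok_c]] <- lower[rs[ok_r], cs[ok_c]] |
      (f[rd[ok_r], cd[ok_c], drop = FALSE] <
         f[rs[ok_r], cs[ok_c], drop = FALSE])
  }
  lab <- matrix(0L, nr, nc)
  next_id <- 1L
  seen <- matrix(FALSE, nr, nc)
  for (p in which(!lower & !seen)) {
    if (seen[p]) next
    # flood the constant plateau containing p
    comp <- flood_plateau(f, p)
    seen[comp] <- TRUE
    if (!any(lower[comp])) {
      lab[comp] <- next_id
      next_id <- next_id + 1L
    }
  }
  if (next_id == 1L) stop("no regional minimum found (empty image?)")
  label_image(lab, n_basins = next_id - 1L)
}

# indices of the 8-connected constant-value plateau containing linear
# index p0
flood_plateau <- function(f, p0) {
  same <- f == f[p0]
  comp <- .cc_label_cpp(same)
  which(comp == comp[p0])
}

#' Threshold set of an altitude map
#'
#' The set `T_h` of pixels whose altitude is at most `h` — the submerged
#' surface when the flood has reached level `h`.
#'
#' @inheritParams immersion_watershed
#' @param h gray level, between the minimum and maximum altitude.
#' @return Logical matrix, `TRUE` for pixels in `T_h`.
#' @export
threshold_set <- function(g, h) {
  f <- as_altitude_matrix(g)
  if (length(h) != 1L || is.na(h)) stop("`h` must be a single level")
  if (h < min(f) || h > max(f)) {
    stop("`h` outside [hmin, hmax] = [", min(f), ", ", max(f), "]")
  }
  f <= h
}

#' Geodesic influence zones
#'
#' Partitions a pixel domain among labelled marker components: a domain
#' pixel belongs to the zone of the component it is strictly closer to
#' (geodesic distance: shortest 8-connected path within the domain, unit
#' cost per step). Pixels equidistant between two components, or
#' unreachable from all of them, stay unassigned (0).
#'
#' @param domain logical matrix, `TRUE` for pixels of the domain.
#' @param markers integer matrix, positive labels on the marker components
#'   (which must lie inside the domain), 0 elsewhere.
#' @return Integer matrix of zone labels (0 = unassigned).
#' @export
geodesic_influence_zones <- function(domain, markers) {
  if (!is.matrix(domain) || !is.logical(domain)) {
    stop("`domain` must be a logical matrix")
  }
  if (!is.matrix(markers) || !all(dim(markers) == dim(domain))) {
    stop("`markers` must be an integer matrix matching `domain`")
  }
  storage.mode(markers) <- "integer"
  if (!any(markers > 0L)) stop("no marker component given")
  if (any(markers > 0L & !domain)) {
    stop("marker components must be subsets of the domain")
  }
  .influence_zones_cpp(domain, markers)
}

#' Trace the watershed line of interest (diagnostic)
#'
#' On the watershed transform of an MLO region-of-interest gradient, the
#' pectoral muscle edge shows up as a unique watershed line starting on the
#' top row and enclosing the top-left region. This tracer looks for a
#' connected component of watershed pixels touching the top row and returns
#' its right-most pixel per row; the production pipeline uses basin merging
#' instead, and this operation exists to validate that property on
#' phantoms.
#'
#' @param labels a [label_image()].
#' @return A [boundary_curve()] or `NULL` when no watershed line touches
#'   the top row.
#' @export
watershed_line_of_interest <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  ws <- labels$labels == 0L
  if (!any(ws)) return(NULL)
  comp <- .cc_label_cpp(ws)
  top <- comp[1L, ]
  top <- top[top > 0L]
  if (!length(top)) return(NULL)
  # the line enclosing the top-left region is the one surfacing left-most
  # on the top row
  id <- top[1L]
  sel <- comp == id
  rows <- which(apply(sel, 1L, any))
  cols <- vapply(rows, function(r) max(which(sel[r, ])), integer(1))
  boundary_curve(rows, cols)
}
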