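#' Pipeline configuration
#'
#' Bundles the tunable parameters of [run_pipeline()]. The defaults
#' reproduce the reference settings: 256x256 working size and merge
#' constant C = 1.
#'
#' @param side input laterality: `"auto"`, `"left"` or `"right"`.
#' @param working_size working resolution (side length).
#' @param c_constant positive constant of the dynamic merge threshold.
#' @param background_threshold intensity at or below which a pixel is
#'   background (unexposed film or air).
#' @param n_top_rows rows scanned for the skin-air boundary; `NULL` means
#'   `ceiling(working_size/8)`.
#' @param save_intermediate when results are written to disk, also write
#'   the ROI (with its offsets sidecar JSON) and the smoothed gradient.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(side = "auto", working_size = 256L,
                            c_constant = 1, background_threshold = 10L,
                            n_top_rows = NULL, save_intermediate = FALSE) {
  if (!side %in% c("auto", "left", "right")) {
    stop("`side` must be auto, left or right")
  }
  working_size <- as.integer(working_size)
  if (working_size < 32L) stop("`working_size` must be >= 32")
  if (c_constant <= 0) stop("`c_constant` must be positive")
  structure(list(side = side, working_size = working_size,
                 c_constant = c_constant,
                 background_threshold = as.integer(background_threshold),
                 n_top_rows = if (is.null(n_top_rows)) NULL
                              else as.integer(n_top_rows),
                 save_intermediate = isTRUE(save_intermediate)),
            class = "pipeline_config")
}

#' Identify the pectoral muscle in an MLO mammogram
#'
#' End-to-end pipeline: orient to left-MLO, resize to the working
#' resolution, strip the unexposed border, extract the region of interest
#' up to the skin-air boundary, compute the smoothed Sobel gradient, apply
#' the immersion watershed, merge the oversegmented basins from the
#' top-left seed, and extract the muscle boundary. Results are mapped back
#' to the input resolution by nearest-neighbour up-sampling and mirrored
#' back if the input was a right-MLO view.
#'
#' @param input a file path to an 8-bit PGM mammogram, or a
#'   [gray_image()].
#' @param config a [pipeline_config()].
#' @param pixel_mm pixel spacing of the input when read from file.
#' @param out_dir if non-`NULL`, a directory into which the muscle mask
#'   (PGM), boundary (CSV, 0-based), and a JSON run log are written.
#' @return An object of class `pipeline_result` with, among others,
#'   `mask` (logical matrix at input resolution, input orientation),
#'   `boundary` ([boundary_curve()] at input resolution),
#'   `boundary_working` (working-scale curve, left-MLO orientation),
#'   `was_flipped`, `offset_col` (0-based working-scale column offset of
#'   the ROI), `n_basins`, `merge` (the [run_merging()] state) and
#'   `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         pixel_mm = 0.2, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  img <- if (is_gray_image(input)) input else {
    stage("load", load_mammogram(input, pixel_mm))
  }

  orient <- stage("orient", orient_to_left_mlo(img, config$side))
  work <- stage("resize", resize_to_working(orient$image,
                                            config$working_size))
  stripped <- stage("strip_border",
                    strip_unexposed_border(work, config$background_threshold))
  n_top <- if (is.null(config$n_top_rows)) {
    ceiling(stripped$image$height_px / 8)
  } else config$n_top_rows
  skin_col <- stage("skin_air",
                    estimate_skin_air_column(stripped$image, n_top,
                                             config$background_threshold))
  roi <- stage("extract_roi", extract_roi(stripped$image, skin_col))
  roi$offset_col <- roi$offset_col + stripped$offset_col

  grad <- stage("gradient", sobel_gradient_magnitude(roi$image))
  filt <- stage("mean_filter", mean_filter_3x3(grad))
  ws <- stage("watershed", immersion_watershed(filt))
  graph <- stage("pixel_graph", build_pixel_graph(roi$image))
  merge <- stage("merging", run_merging(ws, graph, C = config$c_constant))
  boundary_roi <- stage("boundary", extract_boundary(merge))

  # working-frame mask and boundary (left-MLO orientation)
  wsz <- config$working_size
  mask_work <- matrix(FALSE, wsz, wsz)
  roi_mask <- seed_mask(merge)
  mask_work[seq_len(nrow(roi_mask)),
            roi$offset_col + seq_len(ncol(roi_mask))] <- roi_mask
  boundary_working <- boundary_curve(boundary_roi$row,
                                     boundary_roi$col + roi$offset_col)

  # back to input resolution, then input orientation
  mask_full <- upsample_mask(mask_work, img$height_px, img$width_px)
  if (orient$was_flipped) {
    mask_full <- mask_full[, rev(seq_len(ncol(mask_full))), drop = FALSE]
  }
  boundary_full <- if (orient$was_flipped) {
    flipped_boundary(mask_full)
  } else {
    boundary_from_mask(mask_full)
  }

  res <- structure(
    list(mask = mask_full, boundary = boundary_full,
         mask_working = mask_work, boundary_working = boundary_working,
         was_flipped = orient$was_flipped,
         offset_col = roi$offset_col,
         skin_air_col = skin_col + stripped$offset_col,
         n_basins = ws$n_basins, seed_label = merge$seed_label,
         merge = merge, labels = ws,
         roi = roi, pixel_mm_working = roi$image$pixel_mm,
         pixel_mm_input = img$pixel_mm, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir)
    write_overlay(img, res$boundary, file.path(out_dir, "overlay.pgm"))
    if (config$save_intermediate) {
      write_pgm(roi$image, file.path(out_dir, "roi.pgm"))
      jsonlite::write_json(
        list(offset_row_0based = roi$offset_row,
             offset_col_0based = roi$offset_col,
             pixel_mm = roi$image$pixel_mm),
        file.path(out_dir, "roi.json"), auto_unbox = TRUE, digits = NA)
      gpx <- filt$pixels
      gpx[gpx > 255L] <- 255L
      write_pgm(gpx, file.path(out_dir, "gradient.pgm"))
    }
  }
  res
}

# input image with the identified boundary burnt in at full intensity
write_overlay <- function(img, boundary, path) {
  px <- img$pixels
  px[cbind(boundary$row, boundary$col)] <- 255L
  write_pgm(px, path)
}

# left-most column per row for a flipped (right-MLO) mask: the muscle sits
# at the right, so its boundary is the left-most muscle column
flipped_boundary <- function(mask) {
  rows <- which(apply(mask, 1L, any))
  if (!length(rows)) stop("empty mask")
  cols <- vapply(rows, function(r) min(which(mask[r, ])), integer(1))
  boundary_curve(rows, cols)
}

upsample_mask <- function(mask, nr, nc) {
  src_r <- as.integer(floor((seq_len(nr) - 1L) * nrow(mask) / nr)) + 1L
  src_c <- as.integer(floor((seq_len(nc) - 1L) * ncol(mask) / nc)) + 1L
  mask[src_r, src_c, drop = FALSE]
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pgm(res$mask, file.path(out_dir, "pectoral_mask.pgm"))
  write_boundary_csv(res$boundary, file.path(out_dir, "boundary.csv"))
  write_boundary_csv(res$boundary_working,
                     file.path(out_dir, "boundary_working.csv"))
  log <- list(was_flipped = res$was_flipped,
              offset_col_0based = res$offset_col,
              skin_air_col_0based = res$skin_air_col - 1L,
              n_basins = res$n_basins,
              seed_label = res$seed_label,
              n_merge_passes = res$merge$n_outer,
              pixel_mm_working = res$pixel_mm_working,
              pixel_mm_input = res$pixel_mm_input,
              config = unclass(res$config))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  merge_log <- res$merge$log
  utils::write.csv(merge_log, file.path(out_dir, "merge_log.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %s-MLO input, %d basins -> seed %d (%d px working)\n",
    if (x$was_flipped) "right" else "left",
    x$n_basins, x$seed_label, sum(x$mask_working)))
  invisible(x)
}

#' Evaluate a predicted muscle against ground truth
#'
#' Accepts masks (PGM files or logical matrices) or boundary curves (CSV
#' files or [boundary_curve()] objects) for both sides, derives boundary
#' curves where needed, and reports the area-normalized FP/FN and the
#' Hausdorff distance. The ground-truth area is taken from the truth mask
#' when one is given, otherwise from the truth curve's enclosed area.
#'
#' @param pred,truth file path (`.pgm` mask or `.csv` boundary), logical
#'   matrix, or [boundary_curve()]. When both are directories, the
#'   contained `.pgm`/`.csv` files are paired by sorted name and a
#'   [batch_means()] summary is returned instead.
#' @param pixel_mm pixel spacing for the Hausdorff millimetre value
#'   (0.8 at working scale, 0.2 at full MIAS scale).
#' @param out_json optional path for a JSON report.
#' @return An `evaluation_result` (see [evaluate_boundary()]), or a
#'   `batch_summary` for directory input.
#' @export
run_eval <- function(pred, truth, pixel_mm = 0.8, out_json = NULL) {
  if (is.character(pred) && length(pred) == 1L && dir.exists(pred)) {
    if (!(is.character(truth) && dir.exists(truth))) {
      stop("when `pred` is a directory, `truth` must be one too")
    }
    pf <- sort(list.files(pred, "\\.(pgm|csv)$", full.names = TRUE))
    tf <- sort(list.files(truth, "\\.(pgm|csv)$", full.names = TRUE))
    if (!length(pf) || length(pf) != length(tf)) {
      stop("directories must hold the same number of pgm/csv files")
    }
    per <- Map(function(a, b) run_eval(a, b, pixel_mm), pf, tf)
    summ <- batch_means(unname(per))
    if (!is.null(out_json)) {
      jsonlite::write_json(
        list(n = summ$n, fp_mean = summ$fp_mean, fn_mean = summ$fn_mean,
             hausdorff_mean = summ$hausdorff_mean,
             hausdorff_sd = summ$hausdorff_sd,
             bins = as.list(summ$bins), pixel_mm = pixel_mm),
        out_json, auto_unbox = TRUE, digits = NA)
    }
    return(summ)
  }
  p <- as_eval_input(pred)
  t <- as_eval_input(truth)
  area <- if (!is.null(t$mask)) sum(t$mask) else sum(t$curve$col)
  res <- evaluate_boundary(p$curve, t$curve, truth_area = area,
                           pixel_mm = pixel_mm)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(fp = res$fp, fn = res$fn, hausdorff_px = res$hausdorff_px,
           hausdorff_mm = res$hausdorff_mm, pixel_mm = pixel_mm),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  res
}

as_eval_input <- function(x) {
  if (inherits(x, "boundary_curve")) return(list(curve = x, mask = NULL))
  if (is.matrix(x) && is.logical(x)) {
    return(list(curve = boundary_from_mask(x), mask = x))
  }
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.csv$", x, ignore.case = TRUE)) {
      return(list(curve = read_boundary_csv(x), mask = NULL))
    }
    m <- read_pgm_pixels(x) > 0L
    return(list(curve = boundary_from_mask(m), mask = m))
  }
  stop("cannot interpret evaluation input of class ",
       paste(class(x), collapse = "/"))
}
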