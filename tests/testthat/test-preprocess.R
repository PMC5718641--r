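test_that("gray_image validates its invariants", {
  expect_error(gray_image(matrix(0, 2, 2)), "3x3")
  expect_error(gray_image(matrix(-1, 3, 3)), "\\[0, 255\\]")
  expect_error(gray_image(matrix(300, 3, 3)), "\\[0, 255\\]")
  expect_error(gray_image(matrix(0, 3, 3), pixel_mm = 0), "positive")
  img <- gray_image(matrix(5.0, 3, 3), pixel_mm = 0.2)
  expect_identical(img$pixels[1, 1], 5L)
  expect_identical(dim(img), c(3L, 3L))
})

test_that("PGM round-trips through write_pgm/load_mammogram (P2)", {
  px <- matrix(sample(0:255, 20 * 17, replace = TRUE), 20, 17)
  path <- write_tmp_pgm(px)
  img <- load_mammogram(path, pixel_mm = 0.2)
  expect_identical(img$pixels, matrix(as.integer(px), 20, 17))
  expect_identical(img$pixel_mm, 0.2)
  expect_error(load_mammogram(file.path(tempdir(), "absent.pgm")),
               "no such file")
})

test_that("raw (P5) PGM and malformed files are handled", {
  dir <- withr::local_tempdir()
  px <- matrix(sample(0:255, 12 * 9, replace = TRUE), 12, 9)
  p5 <- file.path(dir, "raw.pgm")
  con <- file(p5, "wb")
  writeChar("P5\n9 12\n255\n", con, eos = NULL)
  writeBin(as.raw(t(px)), con)   # row-major pixel stream
  close(con)
  img <- load_mammogram(p5, 0.2)
  expect_identical(img$pixels, matrix(as.integer(px), 12, 9))

  bad <- file.path(dir, "bad.pgm")
  writeLines(c("P6", "3 3", "255", "0 0 0"), bad)
  expect_error(load_mammogram(bad), "P2 or P5")

  small <- file.path(dir, "small.pgm")
  writeLines(c("P2", "2 2", "255", "0 0 0 0"), small)
  expect_error(load_mammogram(small), "minimum size")
})

test_that("orientation is an exact involution and auto-detects laterality", {
  px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  img <- gray_image(px, 0.2)
  once <- orient_to_left_mlo(img, "right")
  expect_true(once$was_flipped)
  twice <- orient_to_left_mlo(once$image, "right")
  expect_identical(twice$image$pixels, img$pixels)

  same <- orient_to_left_mlo(img, "left")
  expect_false(same$was_flipped)
  expect_identical(same$image$pixels, img$pixels)

  ph <- clean_phantom(noise_sd = 2)
  mirrored <- flip_horizontal(ph$image)
  auto <- orient_to_left_mlo(mirrored, "auto")
  expect_true(auto$was_flipped)
  expect_identical(auto$image$pixels, ph$image$pixels)
  expect_false(orient_to_left_mlo(ph$image, "auto")$was_flipped)
})

test_that("resize_to_working block-averages down and keeps bookkeeping", {
  big <- gray_image(matrix(7L, 512, 512), pixel_mm = 0.2)
  small <- resize_to_working(big, 256L)
  expect_identical(dim(small$pixels), c(256L, 256L))
  expect_true(all(small$pixels == 7L))
  expect_equal(small$pixel_mm, 0.4)
  # physical extent preserved to one part in 1e3
  expect_lt(abs(512 * 0.2 - 256 * small$pixel_mm) / (512 * 0.2), 1e-3)

  same <- resize_to_working(small, 256L)
  expect_identical(same$pixels, small$pixels)

  # 1024 at 0.2 mm -> 256 at 0.8 mm
  huge <- gray_image(matrix(0L, 1024, 1024), pixel_mm = 0.2)
  expect_equal(resize_to_working(huge, 256L)$pixel_mm, 0.8)
  expect_error(resize_to_working(small, 2L), ">= 3")

  # block mean is exact on a checkerboard-of-blocks pattern
  px <- matrix(0L, 8, 8)
  px[1:4, 1:4] <- 100L
  r <- resize_to_working(gray_image(px, 1), 4L)
  expect_identical(r$pixels[1:2, 1:2], matrix(100L, 2, 2))
  expect_true(all(r$pixels[3:4, ] == 0L))
})

test_that("strip_unexposed_border removes leading background columns", {
  px <- matrix(80L, 16, 16)
  px[, 1:5] <- 0L
  res <- strip_unexposed_border(gray_image(px, 0.8))
  expect_identical(res$offset_col, 5L)
  expect_identical(res$image$width_px, 11L)

  no_strip <- strip_unexposed_border(gray_image(matrix(80L, 8, 8), 0.8))
  expect_identical(no_strip$offset_col, 0L)
  expect_identical(no_strip$image$pixels, matrix(80L, 8, 8))

  expect_error(strip_unexposed_border(gray_image(matrix(0L, 8, 8), 0.8)),
               "no breast content")
})

test_that("estimate_skin_air_column finds the right-most breast column", {
  px <- matrix(0L, 20, 130)
  extents <- seq(100L, 118L, by = 2L)
  for (i in seq_along(extents)) px[i, 1:extents[i]] <- 90L
  px[15, 1:125] <- 90L  # beyond n_rows, must be ignored
  expect_identical(estimate_skin_air_column(gray_image(px, 0.8),
                                            n_rows = 10L), 118L)

  bright <- gray_image(matrix(200L, 10, 12), 0.8)
  expect_identical(estimate_skin_air_column(bright, n_rows = 3L), 12L)

  expect_error(estimate_skin_air_column(bright, n_rows = 0L), ">= 1")
  dark_top <- matrix(0L, 10, 10); dark_top[10, ] <- 90L
  expect_error(estimate_skin_air_column(gray_image(dark_top, 0.8),
                                        n_rows = 3L), "no above-threshold")
})

test_that("extract_roi slices the chest-wall rectangle", {
  img <- gray_image(matrix(50L, 256, 256), 0.8)
  roi <- extract_roi(img, 151L)
  expect_identical(dim(roi$image$pixels), c(256L, 151L))
  expect_identical(roi$offset_col, 0L)

  full <- extract_roi(img, 256L)
  expect_identical(full$image$pixels, img$pixels)

  expect_error(extract_roi(img, 1L), "narrower")
  expect_error(extract_roi(img, 300L), "outside")
})

test_that("strip + ROI anchors the top-left pixel inside the muscle on phantoms", {
  batch <- phantom_batch(20, phantom_spec(), master_seed = 3L)
  hit <- vapply(batch, function(ph) {
    st <- strip_unexposed_border(ph$image)
    roi <- extract_roi(st$image, estimate_skin_air_column(st$image))
    ph$truth_mask[1L, st$offset_col + roi$offset_col + 1L]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
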