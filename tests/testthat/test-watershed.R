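test_that("find_regional_minima labels minima plateaus", {
  ramp <- matrix(rep(0:4, each = 5), 5, 5)      # increasing by column
  m <- find_regional_minima(ramp)
  expect_identical(m$n_basins, 1L)
  expect_true(all(m$labels[, 1] == 1L) && all(m$labels[, -1] == 0L))

  flat <- find_regional_minima(matrix(3L, 4, 6))
  expect_identical(flat$n_basins, 1L)
  expect_true(all(flat$labels == 1L))

  two <- matrix(9L, 5, 5); two[1, 1] <- 0L; two[5, 5] <- 0L
  m2 <- find_regional_minima(two)
  expect_identical(m2$n_basins, 2L)
  expect_identical(sum(m2$labels > 0L), 2L)
})

test_that("threshold_set implements T_h with range checks", {
  f <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  expect_true(all(threshold_set(f, 3)))
  expect_identical(threshold_set(f, 0), f == 0L)
  expect_identical(threshold_set(f, 1), f <= 1L)
  expect_error(threshold_set(f, 4), "hmin")
  expect_error(threshold_set(f, -1), "hmin")
})

test_that("geodesic influence zones follow strict-inequality semantics", {
  dom <- matrix(TRUE, 1, 5)
  mk <- matrix(0L, 1, 5); mk[1, 1] <- 1L; mk[1, 5] <- 2L
  iz <- geodesic_influence_zones(dom, mk)
  expect_identical(as.vector(iz), c(1L, 1L, 0L, 2L, 2L))  # centre is a tie

  mk1 <- matrix(0L, 1, 5); mk1[1, 1] <- 1L
  expect_true(all(geodesic_influence_zones(dom, mk1) == 1L))

  # disconnected domain halves each belong to their own component
  dom2 <- matrix(TRUE, 3, 7); dom2[, 4] <- FALSE
  mk2 <- matrix(0L, 3, 7); mk2[2, 1] <- 1L; mk2[2, 7] <- 2L
  iz2 <- geodesic_influence_zones(dom2, mk2)
  expect_true(all(iz2[, 1:3] == 1L))
  expect_true(all(iz2[, 5:7] == 2L))
  expect_true(all(iz2[, 4] == 0L))

  expect_error(geodesic_influence_zones(dom, matrix(0L, 1, 5)), "marker")
  expect_error(geodesic_influence_zones(dom2, mk),
               "matching")
})

test_that("immersion watershed handles canonical cases", {
  one <- immersion_watershed(matrix(5L, 4, 4))
  expect_identical(one$n_basins, 1L)
  expect_true(all(one$labels == 1L))

  # valley profile (0,2,5,2,0): two basins meeting at the centre column
  f <- matrix(rep(c(0L, 2L, 5L, 2L, 0L), times = 3), 3, 5, byrow = TRUE)
  ws <- immersion_watershed(f)
  expect_identical(ws$n_basins, 2L)
  expect_true(all(ws$labels[, 3] == 0L))
  expect_true(all(ws$labels[, 1:2] == ws$labels[1, 1]))
  expect_true(all(ws$labels[, 4:5] == ws$labels[1, 4]))

  expect_error(immersion_watershed(matrix(0.5, 3, 3)), "integer")
  g <- sobel_gradient_magnitude(gray_image(matrix(0L, 4, 4), 1))
  expect_error(immersion_watershed(g), "quantized")
})

test_that("watershed equals the brute-force flooding oracle on random images", {
  for (seed in 1:40) {
    f <- random_altitudes(seed)
    got <- immersion_watershed(f)
    want <- oracle_watershed(f)
    expect_true(same_partition(got$labels, want$labels),
                label = paste("partition, seed", seed))
    expect_identical(got$n_basins, want$n_basins,
                     label = paste("basin count, seed", seed))
  }
})

test_that("watershed invariants hold on random images", {
  for (seed in 101:120) {
    f <- random_altitudes(seed, max_alt = 6L)
    ws <- immersion_watershed(f)
    # partition: every pixel is watershed or exactly one basin
    expect_true(all(ws$labels >= 0L & ws$labels <= ws$n_basins))
    # basin count equals the regional minima count
    expect_identical(ws$n_basins, find_regional_minima(f)$n_basins)
    # flooding is monotone in the level
    expect_true(all(diff(ws$assigned_per_level) >= 0L))
    # altitude shift leaves the labelling unchanged
    ws2 <- immersion_watershed(f + 7L)
    expect_identical(ws2$labels, ws$labels)
    # every basin is 8-connected
    for (b in seq_len(ws$n_basins)) {
      expect_identical(max(oracle_cc8(ws$labels == b)), 1L)
    }
  }
})

test_that("watershed line of interest traces the pectoral edge on a clean phantom", {
  ph <- clean_phantom()
  st <- strip_unexposed_border(ph$image)
  roi <- extract_roi(st$image, estimate_skin_air_column(st$image))
  ws <- immersion_watershed(mean_filter_3x3(sobel_gradient_magnitude(roi$image)))
  line <- watershed_line_of_interest(ws)
  expect_s3_class(line, "boundary_curve")
  truth_roi <- ph$truth_boundary$col - st$offset_col
  common <- intersect(line$row, ph$truth_boundary$row)
  expect_gt(length(common), 50)
  dev <- abs(line$col[match(common, line$row)] -
               truth_roi[match(common, ph$truth_boundary$row)])
  expect_lte(max(dev), 2)

  expect_null(watershed_line_of_interest(immersion_watershed(
    matrix(1L, 4, 4))))

  # two-basin vertical split produces a traced vertical line
  f <- matrix(rep(c(0L, 3L, 9L, 3L, 0L), times = 4), 4, 5, byrow = TRUE)
  split_line <- watershed_line_of_interest(immersion_watershed(f))
  expect_identical(split_line$col, rep(3L, 4))
})
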