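test_that("build_pixel_graph enumerates 8-connectivity with |dI| weights", {
  const <- build_pixel_graph(gray_image(matrix(42L, 3, 3), 1))
  expect_identical(length(const$from), 20L)  # 12 axis-aligned + 8 diagonal
  expect_true(all(const$weight == 0L))

  px <- matrix(0L, 3, 3)
  px[1, ] <- c(10L, 14L, 2L)
  g <- build_pixel_graph(gray_image(px, 1))
  w_of <- function(a, b) {
    i <- (g$from == a & g$to == b) | (g$from == b & g$to == a)
    g$weight[i]
  }
  idx <- matrix(seq_len(9), 3, 3)
  expect_identical(w_of(idx[1, 1], idx[1, 2]), 4L)
  expect_identical(w_of(idx[1, 2], idx[1, 3]), 12L)

  n <- 5; m <- 7
  gg <- build_pixel_graph(gray_image(matrix(0L, n, m), 1))
  expected_edges <- n * (m - 1) + m * (n - 1) + 2 * (n - 1) * (m - 1)
  expect_identical(length(gg$from), as.integer(expected_edges))
})

test_that("select_initial_seed picks the top-left basin with raster fallback", {
  lab <- matrix(3L, 4, 4)
  expect_identical(select_initial_seed(label_image(lab, 3L)), 3L)

  lab2 <- matrix(1L, 4, 4); lab2[1, 1] <- 0L; lab2[1, 2] <- 2L
  expect_identical(select_initial_seed(label_image(lab2, 2L)), 2L)

  single <- label_image(matrix(1L, 3, 3), 1L)
  expect_identical(select_initial_seed(single), 1L)
})

test_that("IRA / IRM / DT match their defining equations", {
  # region of two pixels with intensities 10 and 16: one internal edge
  px <- matrix(0L, 3, 3); px[1, 1] <- 10L; px[1, 2] <- 16L
  lab <- matrix(2L, 3, 3); lab[1, 1:2] <- 1L
  g <- build_pixel_graph(gray_image(px, 1))
  li <- label_image(lab, 2L)
  s1 <- region_stats(li, g, 1L)
  expect_identical(s1$size, 2L)
  expect_equal(intra_region_average(s1), 6)

  const_stats <- region_stats(label_image(matrix(1L, 3, 3), 1L),
                              build_pixel_graph(gray_image(matrix(8L, 3, 3),
                                                           1)), 1L)
  expect_equal(intra_region_average(const_stats), 0)

  # single-pixel region: IRA = 0 by convention
  lab3 <- matrix(2L, 3, 3); lab3[1, 1] <- 1L
  s_single <- region_stats(label_image(lab3, 2L), g, 1L)
  expect_equal(intra_region_average(s_single), 0)

  # two adjacent single-pixel regions, intensities 5 and 9: IRM = 4
  px4 <- matrix(200L, 3, 3); px4[1, 1] <- 5L; px4[1, 2] <- 9L
  lab4 <- matrix(3L, 3, 3); lab4[1, 1] <- 1L; lab4[1, 2] <- 2L
  g4 <- build_pixel_graph(gray_image(px4, 1))
  li4 <- label_image(lab4, 3L)
  expect_equal(inter_region_mean(region_stats(li4, g4, 1L),
                                 region_stats(li4, g4, 2L)), 4)

  # seed row of 0s above a neighbour row of 6s: every crossing edge is 6
  px5 <- matrix(0L, 3, 3); px5[2, ] <- 6L; px5[3, ] <- 6L
  lab5 <- matrix(2L, 3, 3); lab5[1, ] <- 1L
  g5 <- build_pixel_graph(gray_image(px5, 1))
  li5 <- label_image(lab5, 2L)
  expect_equal(inter_region_mean(region_stats(li5, g5, 1L),
                                 region_stats(li5, g5, 2L)), 6)

  # non-neighbours error
  labx <- matrix(1L, 3, 3); labx[, 3] <- 3L; labx[, 2] <- 2L
  lix <- label_image(labx, 3L)
  gx <- build_pixel_graph(gray_image(matrix(0L, 3, 3), 1))
  expect_error(inter_region_mean(region_stats(lix, gx, 1L),
                                 region_stats(lix, gx, 3L)),
               "no boundary edge")
})

test_that("dynamic_threshold combines IRA with size-adaptive deltas", {
  fake_stats <- function(label, size, isum, icnt) {
    structure(list(label = label, size = size, internal_edge_sum = isum,
                   internal_edge_count = icnt,
                   boundary = data.frame(neighbour = integer(0),
                                         sum = numeric(0),
                                         count = integer(0))),
              class = "region_stats")
  }
  a <- fake_stats(1L, 10L, 0, 0L)
  b <- fake_stats(2L, 5L, 0, 0L)
  expect_equal(dynamic_threshold(a, b, NR = 20, C = 1), 4)  # max(2, 4)

  sym <- dynamic_threshold(a, fake_stats(2L, 10L, 0, 0L), NR = 20, C = 1)
  expect_equal(sym, 0 + 20 / 10)

  withr::with_seed(5, {
    for (i in 1:10) {
      s1 <- fake_stats(1L, sample(1:50, 1), runif(1, 0, 40), sample(1:9, 1))
      s2 <- fake_stats(2L, sample(1:50, 1), runif(1, 0, 40), sample(1:9, 1))
      NR <- sample(2:100, 1)
      d1 <- dynamic_threshold(s1, s2, NR, C = 1)
      d2 <- dynamic_threshold(s1, s2, NR, C = 2)
      # doubling C doubles the delta terms
      ira1 <- intra_region_average(s1); ira2 <- intra_region_average(s2)
      expect_equal(d2, max(ira1 + 2 * NR / s1$size, ira2 + 2 * NR / s2$size))
      expect_gte(d2, d1)
    }
  })
  expect_error(dynamic_threshold(a, b, NR = 0), "NR")
  expect_error(dynamic_threshold(a, b, NR = 2, C = 0), "positive")
})

test_that("two-basin fixture: contrast 40 edge is never merged", {
  fx <- fixture_two_basin()
  g <- build_pixel_graph(fx$roi)
  s1 <- region_stats(fx$labels, g, 1L)
  s2 <- region_stats(fx$labels, g, 2L)
  expect_equal(intra_region_average(s1), fx$expect$ira_seed, tolerance = 1e-12)
  expect_equal(intra_region_average(s2), fx$expect$ira_nbr, tolerance = 1e-12)
  expect_equal(inter_region_mean(s1, s2), fx$expect$irm, tolerance = 1e-12)
  expect_equal(dynamic_threshold(s1, s2, NR = 2, C = 1), fx$expect$dt,
               tolerance = 1e-12)

  st <- run_merging(fx$labels, g, C = 1)
  expect_identical(sort(which(st$labels == st$seed_label)),
                   sort(fx$expect$seed_cells))
  expect_identical(st$n_outer, 1L)
  expect_equal(st$log$irm, fx$expect$irm)
  expect_equal(st$log$dt, fx$expect$dt)
  expect_false(any(st$log$merged))
})

test_that("three-basin fixture: low-contrast halves merge, background survives", {
  fx <- fixture_three_basin()
  g <- build_pixel_graph(fx$roi)
  sA <- region_stats(fx$labels, g, 1L)
  sB <- region_stats(fx$labels, g, 2L)
  expect_equal(intra_region_average(sA), fx$expect$ira_a, tolerance = 1e-12)
  expect_equal(intra_region_average(sB), fx$expect$ira_b, tolerance = 1e-12)
  expect_equal(inter_region_mean(sA, sB), fx$expect$irm_ab, tolerance = 1e-12)
  expect_equal(dynamic_threshold(sA, sB, NR = 3, C = 1), fx$expect$dt_ab,
               tolerance = 1e-12)

  st <- run_merging(fx$labels, g, C = 1)
  expect_identical(sort(which(st$labels == st$seed_label)),
                   sort(fx$expect$seed_cells))
  expect_identical(st$n_outer, 2L)

  # the logged decisions replay the hand computation
  expect_equal(st$log$irm, c(fx$expect$irm_ab, fx$expect$irm_seed_c),
               tolerance = 1e-12)
  expect_equal(st$log$dt, c(fx$expect$dt_ab, fx$expect$dt_seed_c),
               tolerance = 1e-12)
  expect_identical(st$log$merged, c(TRUE, FALSE))

  # merged-seed statistics agree with a from-scratch recomputation
  s_seed <- region_stats(st$labels, g, st$seed_label)
  expect_equal(intra_region_average(s_seed), fx$expect$ira_seed2,
               tolerance = 1e-12)
  expect_identical(st$stats$size[st$seed_label], s_seed$size)
  expect_equal(st$stats$internal_edge_sum[st$seed_label],
               s_seed$internal_edge_sum)
  expect_identical(st$stats$internal_edge_count[st$seed_label],
                   as.integer(s_seed$internal_edge_count))
})

test_that("incremental statistics match from-scratch recomputation after merging", {
  withr::with_seed(31, {
    for (i in 1:5) {
      f <- matrix(sample(0:3, 8 * 8, replace = TRUE), 8, 8)
      ws <- immersion_watershed(f)
      px <- matrix(sample(0:60, 64, replace = TRUE), 8, 8)
      g <- build_pixel_graph(gray_image(px, 1))
      st <- run_merging(ws, g, C = 1)
      s_seed <- region_stats(st$labels, g, st$seed_label)
      expect_identical(st$stats$size[st$seed_label], s_seed$size)
      expect_equal(st$stats$internal_edge_sum[st$seed_label],
                   s_seed$internal_edge_sum)
      expect_identical(as.integer(st$stats$internal_edge_count[st$seed_label]),
                       as.integer(s_seed$internal_edge_count))
    }
  })
})

test_that("merging is deterministic, order-robust, and terminates within NR passes", {
  fx2 <- fixture_two_basin(); fx3 <- fixture_three_basin()
  for (fx in list(fx2, fx3)) {
    g <- build_pixel_graph(fx$roi)
    a <- run_merging(fx$labels, g, C = 1)
    b <- run_merging(fx$labels, g, C = 1)
    expect_identical(a$labels, b$labels)
    rev_order <- run_merging(fx$labels, g, C = 1,
                             neighbour_order = "reverse")
    expect_identical(which(rev_order$labels == rev_order$seed_label),
                     which(a$labels == a$seed_label))
    expect_lte(a$n_outer, fx$labels$n_basins)
  }

  ph <- clean_phantom(noise_sd = 1.5, seed = 21L, size = 96L)
  st <- strip_unexposed_border(ph$image)
  roi <- extract_roi(st$image, estimate_skin_air_column(st$image))
  ws <- immersion_watershed(mean_filter_3x3(sobel_gradient_magnitude(roi$image)))
  g <- build_pixel_graph(roi$image)
  m1 <- run_merging(ws, g)
  m2 <- run_merging(ws, g)
  expect_identical(m1$labels, m2$labels)
  expect_lte(m1$n_outer, ws$n_basins)
  # monotone growth: the seed never shrinks across passes
  sizes <- tapply(m1$log$merged, m1$log$iteration, sum)
  expect_true(all(sizes[-length(sizes)] > 0))
})

test_that("extract_boundary reports the right-most seed column per row", {
  lab <- matrix(2L, 5, 6); lab[, 1:3] <- 1L
  st <- structure(list(labels = lab, seed_label = 1L), class = "merge_state")
  b <- extract_boundary(st)
  expect_identical(b$row, 1:5)
  expect_identical(b$col, rep(3L, 5))

  tri <- matrix(2L, 5, 5)                     # 2 = background basin
  for (r in 1:3) tri[r, 1:(4 - r)] <- 1L
  st2 <- structure(list(labels = tri, seed_label = 1L),
                   class = "merge_state")
  b2 <- extract_boundary(st2)
  expect_identical(b2$row, 1:3)
  expect_identical(b2$col, c(3L, 2L, 1L))

  single <- matrix(2L, 3, 3); single[1, 1] <- 1L
  b3 <- extract_boundary(structure(list(labels = single, seed_label = 1L),
                                   class = "merge_state"))
  expect_identical(nrow(b3), 1L)
  expect_identical(b3$col, 1L)

  # enclosed watershed pixels adjacent to the seed are absorbed first
  withdam <- matrix(2L, 5, 6); withdam[, 1:2] <- 1L; withdam[, 3] <- 0L
  bd <- extract_boundary(structure(list(labels = withdam, seed_label = 1L),
                                   class = "merge_state"))
  expect_identical(bd$col, rep(3L, 5))

  empty <- structure(list(labels = matrix(2L, 3, 3), seed_label = 1L),
                     class = "merge_state")
  expect_error(extract_boundary(empty), "empty seed")
})
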