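# Shared fixture builders: small images, hand-worked merging fixtures.

rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

# two-basin fixture: bright uniform triangle (contains the top-left
# pixel) against a darker uniform field, crossing contrast 40.
# Hand computation from the merge equations (frozen):
#   |seed| = 6, |nbr| = 10, IRA(seed) = IRA(nbr) = 0, IRM = 40,
#   DT = max(0 + 2/6, 0 + 2/10) = 1/3  ->  no merge, seed stays the
#   triangle.
fixture_two_basin <- function() {
  px <- matrix(120L, 4, 4)
  tri <- outer(1:4, 1:4, "+") <= 4
  px[tri] <- 160L
  lab <- matrix(2L, 4, 4)
  lab[tri] <- 1L
  list(roi = gray_image(px, 0.8),
       labels = label_image(lab, n_basins = 2L),
       expect = list(ira_seed = 0, ira_nbr = 0, irm = 40, dt = 1 / 3,
                     seed_cells = which(tri)))
}

# three-basin fixture: the pectoral split into two low-contrast parts
# (single pixel A at 160 and 5-pixel B spanning the rest of columns 1-2
# at 160/158) plus a distinct background C (column 3 at 118).
# Hand-worked values (3x3 grid, 20 edges, weights |dI|):
#   IRA(A) = 0 (single pixel), IRA(B) = 10/8, IRM(A,B) = 4/3,
#   DT(A,B) = max(0 + 3/1, 10/8 + 3/5) = 3          -> merge A+B
#   IRA(A+B) = 14/11, IRM(A+B, C) = 40,
#   DT(A+B, C) = max(14/11 + 3/6, 0 + 3/3) = 14/11 + 1/2  -> no merge
fixture_three_basin <- function() {
  px <- matrix(rep(c(160L, 158L, 118L), each = 3), 3, 3)
  lab <- matrix(rep(c(1L, 2L, 3L), each = 3), 3, 3)
  lab[1, 1] <- 1L; lab[2, 1] <- 2L; lab[3, 1] <- 2L
  lab[, 2] <- 2L; lab[, 3] <- 3L
  lab[1, 1] <- 1L
  list(roi = gray_image(px, 0.8),
       labels = label_image(lab, n_basins = 3L),
       expect = list(ira_a = 0, ira_b = 10 / 8, irm_ab = 4 / 3,
                     dt_ab = 3, ira_seed2 = 14 / 11, irm_seed_c = 40,
                     dt_seed_c = 14 / 11 + 1 / 2,
                     seed_cells = which(lab != 3L)))
}

# clean low-noise phantom for pipeline mechanics tests (the sigma = 5
# default world is exercised in test-acceptance.R)
clean_phantom <- function(noise_sd = 0, seed = 11L, ...) {
  generate_phantom(phantom_spec(noise_sd = noise_sd, rng_seed = seed, ...))
}

write_tmp_pgm <- function(px, dir = withr::local_tempdir(.local_envir =
                                                           parent.frame())) {
  path <- file.path(dir, paste0("img", as.integer(stats::runif(1, 1, 1e6)),
                                ".pgm"))
  write_pgm(px, path)
  path
}
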