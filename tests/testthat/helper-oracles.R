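# Independent brute-force oracles. Everything in this file is written
# against the stated semantics directly, sharing no code with the package
# internals it checks.

# shift a matrix by (dr, dc), filling vacated cells
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

OFFSETS8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# 8-connected components of a logical mask, plain R flood fill
oracle_cc8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r, c), 1)
    lab[r, c] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(8)) {
        rr <- cur[1] + OFFSETS8[k, 1]; cc <- cur[2] + OFFSETS8[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# brute-force immersion watershed: level-by-level flooding with
# synchronous (simultaneous-update) wave growth; a pixel contacted in the
# same step by two or more distinct basins becomes a permanent dam; fresh
# basins are the regional minima whose plateau altitude is the level
oracle_watershed <- function(f) {
  storage.mode(f) <- "integer"
  nr <- nrow(f); nc <- ncol(f)
  lab <- matrix(0L, nr, nc)
  dam <- matrix(FALSE, nr, nc)
  nxt <- 0L
  lvls <- sort(unique(as.vector(f)))

  label_fresh <- function(mask_new, h) {
    comp <- oracle_cc8(mask_new)
    for (id in seq_len(max(comp, 0L))) {
      cells <- comp == id
      if (!any(cells)) next
      # regional minimum: a maximal plateau at altitude h whose outside
      # neighbours are all strictly higher (an equal-altitude outside
      # neighbour means the component is a dam-carved fragment of a
      # larger plateau that touches lower ground)
      ok <- all(f[cells] == h)
      if (ok) {
        nb_of_cells <- matrix(FALSE, nr, nc)
        for (k in seq_len(8)) {
          nb_of_cells <- nb_of_cells |
            shift_mat(cells, -OFFSETS8[k, 1], -OFFSETS8[k, 2], FALSE)
        }
        outside <- nb_of_cells & !cells
        if (any(f[outside] <= h)) ok <- FALSE
      }
      if (ok) {
        nxt <<- nxt + 1L
        lab[cells] <<- nxt
      }
    }
  }

  # base level: components of the global-minimum set
  label_fresh(f == lvls[1], lvls[1])

  for (h in lvls[-1]) {
    cand <- f <= h & lab == 0L & !dam
    repeat {
      # neighbour label summary under the pre-step labelling
      minpos <- matrix(Inf, nr, nc)
      maxpos <- matrix(0L, nr, nc)
      for (k in seq_len(8)) {
        nb <- shift_mat(lab, OFFSETS8[k, 1], OFFSETS8[k, 2], fill = 0L)
        pos <- nb > 0L
        minpos[pos & nb < minpos] <- nb[pos & nb < minpos]
        maxpos <- pmax(maxpos, nb)
      }
      sel <- cand & lab == 0L & !dam & maxpos > 0L
      if (!any(sel)) break
      tie <- sel & (minpos != maxpos)
      take <- sel & !tie
      dam[tie] <- TRUE
      lab[take] <- maxpos[take]
    }
    label_fresh(f <= h & lab == 0L & !dam, h)
  }
  list(labels = lab, n_basins = nxt)
}

# partitions equal up to relabelling: same zero set, and a bijection
# between nonzero labels
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  nz <- a > 0L
  pairs <- unique(cbind(a[nz], b[nz]))
  nrow(pairs) == length(unique(pairs[, 1])) &&
    nrow(pairs) == length(unique(pairs[, 2]))
}

# O(|A| * |B|) Hausdorff distance by explicit double loop
oracle_hausdorff <- function(a, b) {
  directed <- function(x, y) {
    worst <- 0
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y))) {
        d <- sqrt(sum((x[i, ] - y[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(a, b), directed(b, a))
}

# random integer altitude matrix for oracle-equivalence sweeps
random_altitudes <- function(seed, min_side = 5L, max_side = 12L,
                             max_alt = 4L) {
  withr::with_seed(seed, {
    nr <- sample(min_side:max_side, 1L)
    nc <- sample(min_side:max_side, 1L)
    matrix(sample(0:max_alt, nr * nc, replace = TRUE), nr, nc)
  })
}
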