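#' Weighted 8-connected pixel graph of a region of interest
#'
#' The merge criterion is evaluated on the original ROI data, not on the
#' oversegmented label image: vertices are ROI pixels, edges connect
#' 8-neighbours, and the weight of an edge is the absolute intensity
#' difference of its endpoints.
#'
#' @param roi a [gray_image()].
#' @return An object of class `pixel_graph`: `from`, `to` (linear pixel
#'   indices, column-major), `weight`, `nrow`, `ncol`, `intensity`.
#' @export
build_pixel_graph <- function(roi) {
  assert_gray_image(roi)
  px <- roi$pixels
  nr <- nrow(px); nc <- ncol(px)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  horiz_f <- idx[, -nc]; horiz_t <- idx[, -1L]
  vert_f <- idx[-nr, ]; vert_t <- idx[-1L, ]
  diag1_f <- idx[-nr, -nc]; diag1_t <- idx[-1L, -1L]    # down-right
  diag2_f <- idx[-nr, -1L]; diag2_t <- idx[-1L, -nc]    # down-left
  from <- c(horiz_f, vert_f, diag1_f, diag2_f)
  to <- c(horiz_t, vert_t, diag1_t, diag2_t)
  intens <- as.integer(px)
  structure(list(from = from, to = to,
                 weight = abs(intens[from] - intens[to]),
                 nrow = nr, ncol = nc, intensity = intens),
            class = "pixel_graph")
}

#' @export
print.pixel_graph <- function(x, ...) {
  cat(sprintf("<pixel_graph> %d x %d px, %d edges (8-connectivity)\n",
              x$nrow, x$ncol, length(x$from)))
  invisible(x)
}

#' Select the initial seed basin
#'
#' The merging algorithm starts from the catchment basin owning the
#' top-left ROI pixel, which lies inside the pectoral muscle by
#' construction of the ROI. If that pixel is a watershed pixel, the basin
#' of the first non-watershed pixel in raster order (rows, then columns)
#' is used instead.
#'
#' @param labels a [label_image()].
#' @return The seed basin label (integer).
#' @export
select_initial_seed <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  lab <- labels$labels
  if (lab[1L, 1L] > 0L) return(lab[1L, 1L])
  for (r in seq_len(nrow(lab))) {
    nz <- which(lab[r, ] > 0L)
    if (length(nz)) return(lab[r, nz[1L]])
  }
  stop("label image contains no basin")
}

#' Per-region edge statistics
#'
#' From-scratch bookkeeping for one region of a label image over a pixel
#' graph: pixel count, internal edge sum/count (edges with both endpoints
#' inside the region) and, per neighbouring region, the boundary edge
#' sum/count (edges with one endpoint in each region). Watershed pixels
#' (label 0) belong to no region and contribute no edges.
#'
#' @param labels a [label_image()] (or integer matrix of labels).
#' @param graph a [build_pixel_graph()] result for the same ROI.
#' @param label region label of interest.
#' @return An object of class `region_stats` with fields `label`, `size`,
#'   `internal_edge_sum`, `internal_edge_count` and `boundary` (data.frame
#'   `neighbour`, `sum`, `count`).
#' @export
region_stats <- function(labels, graph, label) {
  lab <- if (inherits(labels, "label_image")) labels$labels else labels
  stopifnot(inherits(graph, "pixel_graph"),
            length(lab) == length(graph$intensity))
  label <- as.integer(label)
  size <- sum(lab == label)
  if (size == 0L) stop("label ", label, " not present")
  lf <- lab[graph$from]; lt <- lab[graph$to]
  internal <- lf == label & lt == label
  touches <- xor(lf == label, lt == label)
  other <- ifelse(lf == label, lt, lf)[touches]
  w <- graph$weight[touches]
  keep <- other > 0L
  boundary <- if (any(keep)) {
    agg_sum <- rowsum(w[keep], group = other[keep])
    data.frame(neighbour = as.integer(rownames(agg_sum)),
               sum = as.numeric(agg_sum),
               count = as.integer(table(other[keep])))
  } else {
    data.frame(neighbour = integer(0), sum = numeric(0), count = integer(0))
  }
  structure(list(label = label, size = size,
                 internal_edge_sum = sum(graph$weight[internal]),
                 internal_edge_count = sum(internal),
                 boundary = boundary),
            class = "region_stats")
}

#' Intra-region edge average (IRA)
#'
#' Mean weight of the edges internal to a region — its homogeneity. A
#' region with no internal edge (a single pixel) is perfectly homogeneous
#' and has IRA 0 by convention.
#'
#' @param stats a [region_stats()] object.
#' @return Non-negative scalar.
#' @export
intra_region_average <- function(stats) {
  stopifnot(inherits(stats, "region_stats"))
  if (stats$internal_edge_count == 0L) return(0)
  stats$internal_edge_sum / stats$internal_edge_count
}

#' Inter-region edge mean (IRM)
#'
#' Mean weight of the edges crossing between two regions — their mutual
#' contrast. Errors if the regions share no boundary edge (they are not
#' direct neighbours).
#'
#' @param seed_stats,nbr_stats [region_stats()] of the two regions,
#'   computed on the same label image.
#' @return Non-negative scalar.
#' @export
inter_region_mean <- function(seed_stats, nbr_stats) {
  stopifnot(inherits(seed_stats, "region_stats"),
            inherits(nbr_stats, "region_stats"))
  b <- seed_stats$boundary
  i <- match(nbr_stats$label, b$neighbour)
  if (is.na(i) || b$count[i] == 0L) {
    stop("regions ", seed_stats$label, " and ", nbr_stats$label,
         " share no boundary edge")
  }
  b$sum[i] / b$count[i]
}

#' Dynamic merge threshold (DT)
#'
#' Size-adaptive threshold against which the inter-region edge mean is
#' tested: `max(IRA(seed) + C*NR/|seed|, IRA(nbr) + C*NR/|nbr|)`. The
#' delta terms relax the criterion for small regions, letting the many
#' small noise-induced basins merge while large homogeneous regions are
#' held to their own contrast. `NR` is the total number of catchment
#' basins of the watershed output and stays fixed during merging; `C` is a
#' positive constant, 1 by default.
#'
#' @inheritParams inter_region_mean
#' @param NR total number of catchment basins.
#' @param C positive constant.
#' @return Non-negative scalar.
#' @export
dynamic_threshold <- function(seed_stats, nbr_stats, NR, C = 1) {
  stopifnot(inherits(seed_stats, "region_stats"),
            inherits(nbr_stats, "region_stats"))
  if (!is.numeric(NR) || NR < 1) stop("`NR` must be >= 1")
  if (!is.numeric(C) || C <= 0) stop("`C` must be positive")
  max(intra_region_average(seed_stats) + C * NR / seed_stats$size,
      intra_region_average(nbr_stats) + C * NR / nbr_stats$size)
}

#' Merge catchment basins into the pectoral muscle region
#'
#' Seeded region merging: starting from the basin owning the top-left ROI
#' pixel, every neighbouring basin whose inter-region edge mean does not
#' exceed the dynamic threshold is relabelled into the seed; the process
#' repeats while at least one merge occurred, and the final seed is the
#' pectoral muscle. All statistics are evaluated on the original ROI pixel
#' graph. Within one pass the neighbour list is the snapshot taken at the
#' top of the pass, but each merge updates the seed before the next
#' neighbour is tested. Basins adjacent to the seed only through a shared
#' watershed line have no direct crossing edges, so they cannot be
#' merge-tested until an intervening merge absorbs the shared dam pixels
#' into the seed (dam pixels between the seed and a merged basin are
#' relabelled to the seed at merge time).
#'
#' @param labels a [label_image()] from [immersion_watershed()].
#' @param graph the [build_pixel_graph()] of the same ROI.
#' @param C positive constant of the dynamic threshold (default 1).
#' @param neighbour_order order in which a pass visits the seed's
#'   neighbours: increasing label (`"label"`, default) or reversed
#'   (`"reverse"`, for order-robustness checks).
#' @return An object of class `merge_state`: `labels` (final label
#'   matrix; the seed region is the muscle), `seed_label`, `NR`, `C`,
#'   `n_outer` (passes run), `log` (one row per neighbour evaluation:
#'   `iteration`, `neighbour`, `direct_edges`, `irm`, `dt`, `merged`), and
#'   `stats` (final incremental aggregates, for verification).
#' @export
run_merging <- function(labels, graph, C = 1,
                        neighbour_order = c("label", "reverse")) {
  stopifnot(inherits(labels, "label_image"), inherits(graph, "pixel_graph"))
  neighbour_order <- match.arg(neighbour_order)
  if (!is.numeric(C) || C <= 0) stop("`C` must be positive")
  lab <- labels$labels
  if (length(lab) != length(graph$intensity)) {
    stop("label image and pixel graph shapes differ")
  }
  NR <- labels$n_basins
  seed <- select_initial_seed(labels)
  intens <- graph$intensity

  nr <- nrow(lab); nc <- ncol(lab)
  ## --- incremental aggregates ---------------------------------------
  size <- tabulate(lab, nbins = NR)
  lf <- lab[graph$from]; lt <- lab[graph$to]
  internal <- lf > 0L & lf == lt
  isum <- numeric(NR); icnt <- integer(NR)
  if (any(internal)) {
    s <- rowsum(graph$weight[internal], group = lf[internal])
    ids <- as.integer(rownames(s))
    isum[ids] <- s
    icnt[ids] <- tabulate(lf[internal], nbins = NR)[ids]
  }
  # pair aggregates keyed "a|b" with a < b; nbrs[[r]] = adjacent regions
  cross <- lf > 0L & lt > 0L & lf != lt
  psum <- new.env(parent = emptyenv())
  pcnt <- new.env(parent = emptyenv())
  # per-region lists hold integer(0), never NULL: assigning NULL into a
  # list deletes the element and shifts all later regions
  nbrs <- rep(list(integer(0)), NR)
  if (any(cross)) {
    pa <- pmin(lf[cross], lt[cross]); pb <- pmax(lf[cross], lt[cross])
    key <- paste0(pa, "|", pb)
    s <- rowsum(graph$weight[cross], group = key)
    cnts <- rowsum(rep(1L, length(key)), group = key)
    for (i in seq_len(nrow(s))) {
      k <- rownames(s)[i]
      assign(k, s[i, 1L], envir = psum)
      assign(k, cnts[i, 1L], envir = pcnt)
    }
    pair_first <- !duplicated(key)
    for (i in which(pair_first)) {
      a <- pa[i]; b <- pb[i]
      nbrs[[a]] <- c(nbrs[[a]], b)
      nbrs[[b]] <- c(nbrs[[b]], a)
    }
  }
  pkey <- function(a, b) {
    if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
  }
  pget <- function(env, k) {
    if (exists(k, envir = env, inherits = FALSE)) {
      get(k, envir = env, inherits = FALSE)
    } else 0
  }
  padd <- function(a, b, ds, dc) {
    k <- pkey(a, b)
    assign(k, pget(psum, k) + ds, envir = psum)
    assign(k, pget(pcnt, k) + dc, envir = pcnt)
  }
  pdel <- function(a, b) {
    k <- pkey(a, b)
    if (exists(k, envir = psum, inherits = FALSE)) rm(list = k, envir = psum)
    if (exists(k, envir = pcnt, inherits = FALSE)) rm(list = k, envir = pcnt)
  }

  # region pixel lists (relabelling without full-matrix scans)
  pix <- rep(list(integer(0)), NR)
  nz <- which(lab > 0L)
  pix_split <- split(nz, lab[nz])
  pix[as.integer(names(pix_split))] <- pix_split

  # watershed pixels: 8-neighbour indices and per-region adjacency lists
  dam_idx <- which(lab == 0L)
  still_dam <- rep(TRUE, length(dam_idx))
  dam_nbr <- neighbour_index_matrix(nr, nc, dam_idx)
  dam_adj <- rep(list(integer(0)), NR)   # region -> dam rows adjacent to it
  if (length(dam_idx)) {
    nl <- matrix(lab[dam_nbr], nrow = length(dam_idx))
    dr <- row(nl)[!is.na(nl) & nl > 0L]
    dl <- nl[!is.na(nl) & nl > 0L]
    keep <- !duplicated(cbind(dr, dl))
    adj_split <- split(dr[keep], dl[keep])
    dam_adj[as.integer(names(adj_split))] <- adj_split
  }

  nbr_pixels <- function(p) {
    r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
    rr <- rep(r, 8L) + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    cc <- rep(c, 8L) + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }

  absorb_dam_into_seed <- function(rows) {
    # relabel shared dam pixels to the seed, updating aggregates from the
    # pixel edges they bring in (weights recomputed from intensities; the
    # underlying graph is 8-connectivity with absolute-difference
    # weights); an edge between two absorbed pixels is counted once
    ps <- dam_idx[rows]
    lab[ps] <<- seed
    still_dam[rows] <<- FALSE
    size[seed] <<- size[seed] + length(ps)
    pix[[seed]] <<- c(pix[[seed]], ps)
    nbm <- dam_nbr[rows, , drop = FALSE]
    ok <- !is.na(nbm)
    p_v <- matrix(rep(ps, 8L), ncol = 8L)[ok]
    q_v <- nbm[ok]
    lq <- lab[q_v]
    w <- abs(intens[p_v] - intens[q_v])
    batch_q <- q_v %in% ps
    int_sel <- lq == seed & (!batch_q | q_v < p_v)
    isum[seed] <<- isum[seed] + sum(w[int_sel])
    icnt[seed] <<- icnt[seed] + sum(int_sel)
    cr_sel <- lq > 0L & lq != seed
    if (any(cr_sel)) {
      s <- rowsum(w[cr_sel], group = lq[cr_sel])
      cnts <- rowsum(rep(1L, sum(cr_sel)), group = lq[cr_sel])
      for (i in seq_len(nrow(s))) {
        x <- as.integer(rownames(s)[i])
        padd(seed, x, s[i, 1L], cnts[i, 1L])
        if (!(x %in% nbrs[[seed]])) {
          nbrs[[seed]] <<- c(nbrs[[seed]], x)
          nbrs[[x]] <<- c(nbrs[[x]], seed)
        }
      }
    }
  }

  merge_into_seed <- function(b) {
    # dam pixels shared between seed and b (snapshot before relabelling)
    shared <- intersect(dam_adj[[seed]], dam_adj[[b]])
    shared <- shared[still_dam[shared]]
    isum[seed] <<- isum[seed] + isum[b] + pget(psum, pkey(seed, b))
    icnt[seed] <<- icnt[seed] + icnt[b] + pget(pcnt, pkey(seed, b))
    pdel(seed, b)
    size[seed] <<- size[seed] + size[b]
    size[b] <<- 0L
    for (x in setdiff(nbrs[[b]], seed)) {
      padd(seed, x, pget(psum, pkey(b, x)), pget(pcnt, pkey(b, x)))
      pdel(b, x)
      nbrs[[x]] <<- setdiff(nbrs[[x]], b)
      if (!(x %in% nbrs[[seed]])) {
        nbrs[[seed]] <<- c(nbrs[[seed]], x)
        nbrs[[x]] <<- c(nbrs[[x]], seed)
      }
    }
    nbrs[[seed]] <<- setdiff(nbrs[[seed]], b)
    nbrs[[b]] <<- integer(0)
    lab[pix[[b]]] <<- seed
    pix[[seed]] <<- c(pix[[seed]], pix[[b]])
    pix[[b]] <<- integer(0)
    dam_adj[[seed]] <<- union(dam_adj[[seed]], dam_adj[[b]])
    dam_adj[[b]] <<- integer(0)
    if (length(shared)) absorb_dam_into_seed(shared)
  }

  ira <- function(r) if (icnt[r] == 0L) 0 else isum[r] / icnt[r]

  # Contrast between the seed and a neighbour separated by a watershed
  # line with no direct crossing edges: mean absolute intensity
  # difference over the pixel pairs (one in each region) flanking the
  # shared dam pixels. These two-hop pairs stand in for Eq.-13 crossing
  # edges, which cannot exist across a one-pixel dam; without them,
  # dam-separated basins could never be merge-tested at all.
  dam_mediated_irm <- function(b, shared) {
    tot <- 0; cnt <- 0L
    for (ri in shared) {
      nbp <- nbr_pixels(dam_idx[ri])
      lq <- lab[nbp]
      us <- nbp[lq == seed]; vb <- nbp[lq == b]
      if (length(us) && length(vb)) {
        d <- abs(outer(intens[us], intens[vb], "-"))
        tot <- tot + sum(d)
        cnt <- cnt + length(d)
      }
    }
    if (cnt == 0L) return(NULL)
    list(irm = tot / cnt, n = cnt)
  }

  # audit log as growable parallel vectors
  log_cap <- 256L; log_n <- 0L
  log_it <- integer(log_cap); log_nb <- integer(log_cap)
  log_de <- integer(log_cap); log_irm <- numeric(log_cap)
  log_dt <- numeric(log_cap); log_mg <- logical(log_cap)
  log_push <- function(it, nb, de, irm, dt, mg) {
    if (log_n == log_cap) {
      log_cap <<- log_cap * 2L
      length(log_it) <<- log_cap; length(log_nb) <<- log_cap
      length(log_de) <<- log_cap; length(log_irm) <<- log_cap
      length(log_dt) <<- log_cap; length(log_mg) <<- log_cap
    }
    log_n <<- log_n + 1L
    log_it[log_n] <<- it; log_nb[log_n] <<- nb; log_de[log_n] <<- de
    log_irm[log_n] <<- irm; log_dt[log_n] <<- dt; log_mg[log_n] <<- mg
  }
  n_outer <- 0L
  repeat {
    n_outer <- n_outer + 1L
    if (n_outer > NR) {
      stop("merging failed to terminate within NR = ", NR, " passes")
    }
    # snapshot of the seed's neighbourhood: direct-edge neighbours plus
    # basins sharing a watershed pixel with the seed
    direct <- sort(nbrs[[seed]])
    dam_only <- integer(0)
    sh_rows <- dam_adj[[seed]]
    sh_rows <- sh_rows[still_dam[sh_rows]]
    if (length(sh_rows)) {
      nl <- lab[dam_nbr[sh_rows, , drop = FALSE]]
      touching <- unique(nl[!is.na(nl) & nl > 0L])
      dam_only <- sort(setdiff(touching[touching != seed], direct))
    }
    if (neighbour_order == "reverse") {
      direct <- rev(direct); dam_only <- rev(dam_only)
    }
    merged_any <- FALSE
    for (b in direct) {
      if (size[b] == 0L) next            # already merged this pass
      cnt <- pget(pcnt, pkey(seed, b))
      if (cnt == 0L) next
      irm <- pget(psum, pkey(seed, b)) / cnt
      dt <- max(ira(seed) + C * NR / size[seed],
                ira(b) + C * NR / size[b])
      do_merge <- irm <= dt
      log_push(n_outer, b, cnt, irm, dt, do_merge)
      if (do_merge) {
        merge_into_seed(b)
        merged_any <- TRUE
      }
    }
    for (b in dam_only) {
      if (size[b] == 0L) next
      shared <- intersect(dam_adj[[seed]], dam_adj[[b]])
      shared <- shared[still_dam[shared]]
      dm <- dam_mediated_irm(b, shared)
      if (is.null(dm)) next
      dt <- max(ira(seed) + C * NR / size[seed],
                ira(b) + C * NR / size[b])
      do_merge <- dm$irm <= dt
      log_push(n_outer, b, 0L, dm$irm, dt, do_merge)
      if (do_merge) {
        merge_into_seed(b)
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }

  keep <- seq_len(log_n)
  log_df <- data.frame(iteration = log_it[keep], neighbour = log_nb[keep],
                       direct_edges = log_de[keep], irm = log_irm[keep],
                       dt = log_dt[keep], merged = log_mg[keep])
  structure(list(labels = lab, seed_label = seed, NR = NR, C = C,
                 n_outer = n_outer, log = log_df,
                 stats = list(size = size, internal_edge_sum = isum,
                              internal_edge_count = icnt)),
            class = "merge_state")
}

#' @export
print.merge_state <- function(x, ...) {
  cat(sprintf(
    "<merge_state> seed %d: %d px after %d passes (NR = %d, C = %g)\n",
    x$seed_label, sum(x$labels == x$seed_label), x$n_outer, x$NR, x$C))
  invisible(x)
}

# linear indices of the 8 neighbours of each given pixel (NA off-grid)
neighbour_index_matrix <- function(nr, nc, idx) {
  if (!length(idx)) return(matrix(integer(0), 0, 8))
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  out <- matrix(NA_integer_, length(idx), 8L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    k <- k + 1L
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out[ok, k] <- (cc[ok] - 1L) * nr + rr[ok]
  }
  out
}

#' Extract the pectoral boundary from a merge result
#'
#' Watershed pixels adjacent to the final seed are absorbed into it (one
#' pass), then the right-most seed column of every row intersecting the
#' seed is reported.
#'
#' @param state a [run_merging()] result.
#' @return A [boundary_curve()].
#' @export
extract_boundary <- function(state) {
  stopifnot(inherits(state, "merge_state"))
  boundary_from_mask(seed_mask(state))
}

#' Binary muscle mask of a merge result
#'
#' @param state a [run_merging()] result.
#' @param absorb_dams absorb watershed pixels adjacent to the seed (one
#'   pass) before returning, as done for boundary extraction.
#' @return Logical matrix, `TRUE` on the muscle.
#' @export
seed_mask <- function(state, absorb_dams = TRUE) {
  stopifnot(inherits(state, "merge_state"))
  lab <- state$labels
  m <- lab == state$seed_label
  if (!any(m)) stop("empty seed region")
  if (absorb_dams) {
    dam <- which(lab == 0L)
    if (length(dam)) {
      nbm <- neighbour_index_matrix(nrow(lab), ncol(lab), dam)
      near <- rowSums(matrix(m[nbm], nrow = length(dam)),
                      na.rm = TRUE) > 0L
      m[dam[near]] <- TRUE
    }
  }
  m
}
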