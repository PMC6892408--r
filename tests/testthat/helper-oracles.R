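# Independent reference implementations used as oracles. Deliberately
# slow and simple: none shares code with the package internals.

# stack-based flood fill with configurable connectivity
flood_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    nb <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  nextlab <- 0L
  # raster order: by rows, then columns
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    nextlab <- nextlab + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nextlab
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc2 <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= h && cc2 >= 1 && cc2 <= w &&
            mask[rr, cc2] && lab[rr, cc2] == 0L) {
          lab[rr, cc2] <- nextlab
          stack[[length(stack) + 1L]] <- c(rr, cc2)
        }
      }
    }
  }
  lab
}

# exhaustive-search Otsu: maximise between-class variance over candidate
# thresholds placed between the 256 histogram bins
otsu_brute <- function(map, levels = 256) {
  rg <- range(map)
  cand <- seq(rg[1], rg[2], length.out = levels + 1)
  cand <- cand[-c(1, length(cand))]
  best <- -Inf; best_t <- cand[1]
  for (t in cand) {
    lo <- map[map <= t]; hi <- map[map > t]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# literal step-up Benjamini-Hochberg
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# multi-source BFS partition oracle for a shared Iba1 component:
# per-pixel queue implementation, independent of the package's
# frontier-vectorised version. Seeds are component pixels within
# radius_um of a nucleus, labelled by the Euclidean-nearest qualifying
# nucleus (tie -> lower id); hop ties -> lower id via ordered expansion.
bfs_partition_oracle <- function(comp_mask, nuclei_idx_list, radius_um, mpp) {
  h <- nrow(comp_mask); w <- ncol(comp_mask)
  radius <- radius_um / mpp
  pix <- which(comp_mask)
  pr <- (pix - 1L) %% h + 1L; pc <- (pix - 1L) %/% h + 1L
  nlab <- length(nuclei_idx_list)
  dmin <- rep(Inf, length(pix)); sl <- rep(0L, length(pix))
  for (k in seq_len(nlab)) {
    ni <- nuclei_idx_list[[k]]
    nr <- (ni - 1L) %% h + 1L; nc <- (ni - 1L) %/% h + 1L
    for (i in seq_along(pix)) {
      d <- sqrt(min((pr[i] - nr)^2 + (pc[i] - nc)^2))
      if (d <= radius && (d < dmin[i] - 1e-12 ||
                          (abs(d - dmin[i]) <= 1e-12 && k < sl[i]))) {
        dmin[i] <- d; sl[i] <- k
      }
    }
  }
  lab <- matrix(0L, h, w)
  lab[pix[sl > 0L]] <- sl[sl > 0L]
  queue <- pix[sl > 0L][order(lab[pix[sl > 0L]])]
  while (length(queue)) {
    nxt <- integer(0)
    # expand one BFS level; among same-level competitors the lower label
    # wins because pixels are claimed in increasing label order
    for (q in queue[order(lab[queue])]) {
      qr <- (q - 1L) %% h + 1L; qc <- (q - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- qr + dr; cc <- qc + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (!comp_mask[rr, cc]) next
        ii <- (cc - 1L) * h + rr
        if (lab[ii] == 0L) { lab[ii] <- lab[q]; nxt <- c(nxt, ii) }
      }
    }
    queue <- nxt
  }
  lab
}

# tiny well-separated noise-free scene used across tests
clean_scene_params <- function(seed, n_cells = 4, size = 400L) {
  synth_params(n_cells = n_cells, seed = seed, noise_sd = 0,
               background_od = 0, min_separation_um = 60,
               image_size_px = c(size, size))
}
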