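# Nucleus detection and the contiguity rule: every Iba1-positive connected
# component whose minimum Euclidean distance to a Pu.1-positive nucleus is
# at most 2 um is attributed, whole, to that cell; components reachable
# from two or more nuclei are partitioned by within-component (geodesic)
# distance to the nearest qualifying nucleus; everything else is
# "non-process" Iba1.

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels touching diagonally are merged with a union-find pass, then
# relabelled 1..K in raster (row-major) order of each component's first
# pixel. Thin 1-px diagonal processes must stay contiguous, hence 8-conn.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- EBImage::bwlabel(mask)
  if (inherits(lab, "Image")) lab <- EBImage::imageData(lab)
  lab <- matrix(as.integer(lab), h, w)
  nlab <- max(lab)
  if (nlab == 0L) return(lab)

  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]     # (i,j) vs (i+1,j+1)
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]     # (i,j+1) vs (i+1,j)
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))

  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  fg <- which(lab > 0L)
  lab[fg] <- root[lab[fg]]

  # raster-order ids
  rows <- (fg - 1L) %% h + 1L
  cols <- (fg - 1L) %/% h + 1L
  rowmajor <- (rows - 1L) * w + cols
  first <- tapply(rowmajor, lab[fg], min)
  old <- as.integer(names(first))
  new <- integer(nlab)
  new[old[order(first)]] <- seq_along(old)
  lab[fg] <- new[lab[fg]]
  lab
}

#' Detect Pu.1-positive nuclei in a thresholded mask
#'
#' Connected components (8-connectivity) of the Pu.1 mask, kept when their
#' physical area lies in `[min_area_um2, max_area_um2]` (inclusive). Ids
#' are assigned in raster order of each component's first pixel.
#'
#' @param pu1_mask A [threshold_channel()] `binary_mask` of the Pu.1
#'   channel (must carry `microns_per_pixel`).
#' @param min_area_um2,max_area_um2 Area window in square micrometres,
#'   `0 <= min < max`. Defaults bracket plausible microglial nuclei.
#' @return Object of class `nucleus_set`: list of records, each with `id`,
#'   `idx` (pixel indices, column-major), `centroid` `(row, col)`,
#'   `area_um2`; attributes carry the scale and mask dimensions.
#' @export
detect_nuclei <- function(pu1_mask, min_area_um2 = 5, max_area_um2 = 200) {
  stopifnot(inherits(pu1_mask, "binary_mask"),
            min_area_um2 >= 0, min_area_um2 < max_area_um2)
  mpp <- pu1_mask$microns_per_pixel
  if (is.null(mpp)) stop("pu1_mask has no microns_per_pixel")
  h <- nrow(pu1_mask$mask)
  lab <- label_components(pu1_mask$mask)
  recs <- list()
  if (max(lab) > 0L) {
    fg <- which(lab > 0L)
    groups <- split(fg, lab[fg])          # names "1".."K" in raster order
    groups <- groups[order(as.integer(names(groups)))]
    id <- 0L
    for (idx in groups) {
      area <- length(idx) * mpp^2
      if (area < min_area_um2 || area > max_area_um2) next
      id <- id + 1L
      rows <- (idx - 1L) %% h + 1L
      cols <- (idx - 1L) %/% h + 1L
      recs[[id]] <- list(id = id, idx = idx,
                         centroid = c(mean(rows), mean(cols)),
                         area_um2 = area)
    }
  }
  structure(recs, class = "nucleus_set",
            microns_per_pixel = mpp, mask_dim = dim(pu1_mask$mask))
}

#' Assign Iba1 immunoreactivity to nuclei by the contiguity rule
#'
#' An Iba1 connected component (8-connectivity) is attributed to a cell
#' when its minimum Euclidean distance to any pixel of that cell's nucleus
#' is `<= radius_um` (inclusive; distances are physical, via the mask
#' scale). A component reachable from exactly one nucleus is assigned to it
#' wholly; a component reachable from several nuclei is partitioned by
#' breadth-first (geodesic, within-component, 8-neighbour) distance from
#' the pixels nearest each qualifying nucleus, ties going to the lower
#' nucleus id. Iba1 pixels attributed to no nucleus form the non-process
#' mask. Cell masks plus the non-process mask tile the Iba1 mask exactly;
#' this partition identity is asserted on every run.
#'
#' @param iba1_mask A `binary_mask` of the Iba1 channel.
#' @param nuclei A [detect_nuclei()] `nucleus_set` on the same pixel grid
#'   and scale (mismatch is an error).
#' @param radius_um Contiguity radius in micrometres (default 2).
#' @return Object of class `segmentation_result`: `cells` (one per nucleus:
#'   `nucleus`, `process_idx`, morphometrics filled by [measure_cells()]),
#'   `non_process_idx`, grid/scale metadata and a parameter echo.
#' @export
assign_processes <- function(iba1_mask, nuclei, radius_um = 2.0) {
  stopifnot(inherits(iba1_mask, "binary_mask"),
            inherits(nuclei, "nucleus_set"), radius_um >= 0)
  mpp <- iba1_mask$microns_per_pixel
  if (is.null(mpp)) stop("iba1_mask has no microns_per_pixel")
  if (!isTRUE(all.equal(mpp, attr(nuclei, "microns_per_pixel"))))
    stop("scale mismatch between iba1 mask and nuclei")
  if (!all(dim(iba1_mask$mask) == attr(nuclei, "mask_dim")))
    stop("shape mismatch between iba1 mask and nuclei")

  mask <- iba1_mask$mask
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(mask)
  ncomp <- max(lab)
  radius_px <- radius_um / mpp
  marg <- as.integer(ceiling(radius_px)) + 1L

  # qualifying (component, nucleus) pairs with the Euclidean distance of
  # every near-nucleus component pixel, from a per-nucleus local distance
  # transform (nucleus pixels all lie inside the crop, so crop distances
  # to the nucleus are exact)
  pair_comp <- integer(0); pair_nuc <- integer(0)
  seeds <- list()                          # per nucleus: idx + dist_um
  for (nuc in nuclei) {
    rows <- (nuc$idx - 1L) %% h + 1L
    cols <- (nuc$idx - 1L) %/% h + 1L
    r0 <- max(1L, min(rows) - marg); r1 <- min(h, max(rows) + marg)
    c0 <- max(1L, min(cols) - marg); c1 <- min(w, max(cols) + marg)
    ch <- r1 - r0 + 1L
    nm <- matrix(1, ch, c1 - c0 + 1L)
    nm[(cols - c0) * ch + (rows - r0 + 1L)] <- 0   # nucleus px = background
    d <- EBImage::distmap(nm)
    if (inherits(d, "Image")) d <- EBImage::imageData(d)
    near <- which(d * mpp <= radius_um)
    lr <- (near - 1L) %% ch + r0
    lc <- (near - 1L) %/% ch + c0
    gidx <- (lc - 1L) * h + lr
    on_comp <- lab[gidx] > 0L
    gidx <- gidx[on_comp]
    comps <- unique(lab[gidx])
    pair_comp <- c(pair_comp, comps)
    pair_nuc <- c(pair_nuc, rep(nuc$id, length(comps)))
    seeds[[nuc$id]] <- list(idx = gidx, dist_um = d[near][on_comp] * mpp)
  }

  assign_lab <- matrix(0L, h, w)
  if (length(pair_comp)) {
    nuc_per_comp <- split(pair_nuc, pair_comp)
    for (cs in names(nuc_per_comp)) {
      comp <- as.integer(cs)
      nucs <- sort(nuc_per_comp[[cs]])
      if (length(nucs) == 1L) {
        assign_lab[lab == comp] <- nucs
      } else {
        assign_lab <- partition_component(lab, comp, nucs, seeds, assign_lab)
      }
    }
  }

  cells <- lapply(nuclei, function(nuc) {
    list(nucleus = nuc, process_idx = integer(0),
         total_iba1_area_um2 = NA_real_, process_area_um2 = NA_real_,
         process_perimeter_um = NA_real_)
  })
  assigned <- which(assign_lab > 0L)
  if (length(assigned)) {
    by_nuc <- split(assigned, assign_lab[assigned])
    for (ns in names(by_nuc))
      cells[[as.integer(ns)]]$process_idx <- by_nuc[[ns]]
  }
  non_process_idx <- which(mask & assign_lab == 0L)

  # partition identity, pixel-exact
  n_iba1 <- sum(mask)
  n_parts <- length(non_process_idx) +
    sum(vapply(cells, function(x) length(x$process_idx), 0L))
  stopifnot(n_parts == n_iba1)

  structure(list(
    cells = cells,
    non_process_idx = non_process_idx,
    dim = c(h, w),
    microns_per_pixel = mpp,
    n_iba1_px = n_iba1,
    params = list(radius_um = radius_um, connectivity = 8L,
                  iba1_threshold = iba1_mask$threshold)
  ), class = "segmentation_result")
}

# multi-source BFS over the 8-neighbour pixel graph restricted to one
# component; seeds are the component pixels within the contiguity radius of
# each qualifying nucleus (nearest nucleus wins a seed pixel, tie -> lower
# id); unreached-level ties also resolve to the lower id because all
# candidates of a BFS level are reduced together with min-label priority
partition_component <- function(lab, comp, nucs, seeds, assign_lab) {
  h <- nrow(lab); w <- ncol(lab)
  comp_mask <- lab == comp

  sidx <- integer(0); sdist <- numeric(0); snuc <- integer(0)
  for (nid in nucs) {
    s <- seeds[[nid]]
    in_comp <- comp_mask[s$idx]
    sidx <- c(sidx, s$idx[in_comp])
    sdist <- c(sdist, s$dist_um[in_comp])
    snuc <- c(snuc, rep(nid, sum(in_comp)))
  }
  o <- order(sidx, sdist, snuc)
  sidx <- sidx[o]; snuc <- snuc[o]
  keep <- !duplicated(sidx)
  sidx <- sidx[keep]; snuc <- snuc[keep]

  assign_lab[sidx] <- snuc
  frontier <- sidx
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (length(frontier)) {
    fr <- (frontier - 1L) %% h + 1L
    fc <- (frontier - 1L) %/% h + 1L
    nr <- rep(fr, times = 8L) + rep(off_r, each = length(frontier))
    nc <- rep(fc, times = 8L) + rep(off_c, each = length(frontier))
    nl <- rep(assign_lab[frontier], times = 8L)
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    nl <- nl[ok]
    ok2 <- comp_mask[nidx] & assign_lab[nidx] == 0L
    nidx <- nidx[ok2]; nl <- nl[ok2]
    if (!length(nidx)) break
    o <- order(nidx, nl)
    nidx <- nidx[o]; nl <- nl[o]
    keep <- !duplicated(nidx)
    nidx <- nidx[keep]; nl <- nl[keep]
    assign_lab[nidx] <- nl
    frontier <- nidx
  }
  assign_lab
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d cells, %d Iba1 px (%d non-process) @ %.3g um/px\n",
    length(x$cells), x$n_iba1_px, length(x$non_process_idx),
    x$microns_per_pixel))
  invisible(x)
}
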