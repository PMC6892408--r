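# Scene rasterisation for the synthetic dual-stain generator.
#
# Geometry is laid out in continuous pixel coordinates and rasterised by
# pixel-centre membership tests (disc: distance to centre <= r; process:
# distance to a densely sampled polyline <= thickness/2). Continuous
# placement keeps pixel counting an unbiased estimator of continuous area,
# which is what makes the configured effect multipliers recoverable from
# the ground-truth masks.

# pixels (column-major indices) within radius r of continuous centre (cr, cc)
disc_indices <- function(cr, cc, r, h, w) {
  r0 <- max(1L, floor(cr - r)); r1 <- min(h, ceiling(cr + r))
  c0 <- max(1L, floor(cc - r)); c1 <- min(w, ceiling(cc + r))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  rr <- rep(rows, times = length(cols))
  cc2 <- rep(cols, each = length(rows))
  keep <- (rr - cr)^2 + (cc2 - cc)^2 <= r^2
  (cc2[keep] - 1L) * h + rr[keep]
}

# pixels within radius r of any node of a polyline (nodes spaced <= 0.5 px,
# so the union of discs approximates the capsule around the path)
stamp_path <- function(pts, r, h, w) {
  if (nrow(pts) == 0) return(integer(0))
  re <- ceiling(r)
  offs <- expand.grid(dr = -re:re, dc = -re:re)
  n <- nrow(pts); m <- nrow(offs)
  pr <- rep(pts[, 1], each = m); pc <- rep(pts[, 2], each = m)
  ri <- round(pr) + rep(offs$dr, times = n)
  ci <- round(pc) + rep(offs$dc, times = n)
  d2 <- (ri - pr)^2 + (ci - pc)^2
  keep <- d2 <= r^2 & ri >= 1 & ri <= h & ci >= 1 & ci <= w
  unique((ci[keep] - 1L) * h + ri[keep])
}

# meandering process path from the soma edge outward
process_path <- function(center, r_soma, angle, length_px, step = 0.5,
                         jitter_sd = 0.12) {
  n_steps <- max(1L, ceiling(length_px / step))
  th <- angle + cumsum(c(0, stats::rnorm(n_steps - 1, 0, jitter_sd)))
  dr <- cumsum(step * sin(th)); dc <- cumsum(step * cos(th))
  start_r <- center[1] + r_soma * sin(angle)
  start_c <- center[2] + r_soma * cos(angle)
  cbind(c(start_r, start_r + dr), c(start_c, start_c + dc))
}

#' Render one synthetic dual-stain microglia field with exact ground truth
#'
#' Places non-overlapping somata, grows meandering processes of configured
#' thickness, rasterises nucleus/soma/process masks, and renders the scene
#' through the Beer-Lambert model: per-pixel stain concentrations multiply
#' the stain optical-density vectors, a neutral background OD and optional
#' Gaussian OD noise are added, and transmitted 8-bit RGB is
#' `255 * 10^-OD`. Identical parameters and seed give bit-identical output.
#'
#' Cells that cannot be placed without soma overlap after 100 attempts are
#' dropped; the ground truth reflects actual placements.
#'
#' @param params A [synth_params()] object.
#' @param render If `FALSE`, skip RGB rendering and return `image = NULL`
#'   (masks and ground truth only — useful for large simulation studies
#'   that consume ground truth directly). The scene is drawn from the RNG
#'   before rendering noise, so masks are identical either way.
#' @return A list with components:
#'   \describe{
#'     \item{image}{a [calibrated_image()] (region `"other"`).}
#'     \item{ground_truth}{object of class `ground_truth`: per-cell pixel
#'       index sets (`nucleus_idx`, `iba1_idx`, `process_idx`), per-cell
#'       areas/perimeter in physical units, a cell `label_mask` and
#'       `nucleus_label_mask`, region totals and the generating parameters.}
#'   }
#' @export
generate_microglia_image <- function(params, render = TRUE) {
  validate_synth_params(params)
  set.seed(params$seed)
  h <- params$image_size_px[1]; w <- params$image_size_px[2]
  mpp <- params$microns_per_pixel
  r_soma <- params$soma_radius_um / mpp
  r_nuc <- 0.65 * r_soma
  r_proc <- params$process_thickness_um / (2 * mpp)
  len_mu <- params$process_length_um[1] / mpp
  len_sd <- params$process_length_um[2] / mpp

  if (params$n_cells > 0 && (2 * r_soma + 2 > min(h, w)))
    stop("image too small to place any soma at this scale")

  # --- placement: rejection sampling, somata must not overlap
  centers <- matrix(numeric(0), 0, 2)
  min_sep <- if (is.null(params$min_separation_um)) 2 * r_soma + 4
             else max(params$min_separation_um / mpp, 2 * r_soma + 4)
  for (i in seq_len(params$n_cells)) {
    for (try in seq_len(100)) {
      cand <- c(stats::runif(1, 1 + r_soma, h - r_soma),
                stats::runif(1, 1 + r_soma, w - r_soma))
      ok <- nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
              min_sep^2)
      if (ok) { centers <- rbind(centers, cand); break }
    }
  }
  n_placed <- nrow(centers)

  cells <- vector("list", n_placed)
  label_mask <- matrix(0L, h, w)
  nucleus_label_mask <- matrix(0L, h, w)
  for (i in seq_len(n_placed)) {
    ctr <- centers[i, ]
    soma_idx <- disc_indices(ctr[1], ctr[2], r_soma, h, w)
    nuc_idx <- disc_indices(ctr[1], ctr[2], r_nuc, h, w)
    proc_idx <- integer(0)
    if (params$n_processes_per_cell > 0) {
      base_angles <- seq(0, 2 * pi, length.out = params$n_processes_per_cell + 1)
      base_angles <- base_angles[-length(base_angles)] +
        stats::runif(1, 0, 2 * pi)
      for (a in base_angles) {
        len <- min(max(1 / mpp, stats::rnorm(1, len_mu, len_sd)),
                   len_mu + 3 * len_sd)
        pts <- process_path(ctr, r_soma, a + stats::rnorm(1, 0, 0.2), len)
        proc_idx <- c(proc_idx, stamp_path(pts, max(r_proc, 0.5), h, w))
      }
      proc_idx <- setdiff(unique(proc_idx), soma_idx)
    }
    iba1_idx <- c(soma_idx, proc_idx)
    cells[[i]] <- list(
      id = i,
      center_px = ctr,
      nucleus_idx = nuc_idx,
      iba1_idx = iba1_idx,
      process_idx = proc_idx,
      nucleus_area_um2 = length(nuc_idx) * mpp^2,
      iba1_area_um2 = length(iba1_idx) * mpp^2,
      process_area_um2 = length(proc_idx) * mpp^2
    )
    sel <- iba1_idx[label_mask[iba1_idx] == 0L]
    label_mask[sel] <- i
    nucleus_label_mask[nuc_idx] <- i
  }
  # ground-truth perimeter of the full attached mask, same estimator the
  # measurement stage uses
  for (i in seq_len(n_placed)) {
    cells[[i]]$process_perimeter_um <-
      estimate_perimeter(mask_from_idx(cells[[i]]$iba1_idx, h, w), mpp,
                         warn_empty = FALSE)
  }

  gt <- structure(list(
    cells = cells,
    n_cells = n_placed,
    label_mask = label_mask,
    nucleus_label_mask = nucleus_label_mask,
    total_iba1_area_um2 = sum(label_mask > 0) * mpp^2,
    params = params
  ), class = "ground_truth")

  # --- render
  if (!render)
    return(list(image = NULL, ground_truth = gt))
  conc_iba1 <- matrix(0, h, w); conc_pu1 <- matrix(0, h, w)
  for (cell in cells) {
    conc_iba1[cell$iba1_idx] <- 0.8
    conc_pu1[cell$nucleus_idx] <- 0.9
  }
  v <- params$stain_vectors
  px <- array(0, c(h, w, 3))
  for (k in 1:3) {
    od <- v[k, 1] * conc_iba1 + v[k, 2] * conc_pu1 + params$background_od
    if (params$noise_sd > 0)
      od <- od + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
    px[, , k] <- pmin(pmax(round(255 * 10^-pmax(od, 0)), 0), 255)
  }
  list(image = calibrated_image(px, mpp, region = "other"),
       ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells, total Iba1 area %.1f um^2\n",
              x$n_cells, x$total_iba1_area_um2))
  invisible(x)
}

#' Export ground truth as JSON (per-cell records; masks as index lists)
#'
#' @param gt A `ground_truth` object.
#' @param path Output path.
#' @export
ground_truth_to_json <- function(gt, path) {
  cells <- lapply(gt$cells, function(cl)
    cl[c("id", "center_px", "nucleus_area_um2", "iba1_area_um2",
         "process_area_um2", "process_perimeter_um", "nucleus_idx",
         "iba1_idx")])
  jsonlite::write_json(
    list(n_cells = gt$n_cells,
         total_iba1_area_um2 = gt$total_iba1_area_um2,
         microns_per_pixel = gt$params$microns_per_pixel,
         cells = cells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
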