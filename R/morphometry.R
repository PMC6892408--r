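# Perimeter and area measurement of digital masks, and the four per-region
# summary metrics: cells per mm^2, total Iba1 area per nucleus, process
# area per nucleus, process perimeter per nucleus.

# crop a column-major pixel index set to a tight bounding-box matrix
# (1-px pad); perimeter is invariant under this cropping
mask_from_idx <- function(idx, h, w) {
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  r0 <- min(rows); c0 <- min(cols)
  m <- matrix(FALSE, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  m[(cols - c0 + 1L) * nrow(m) + (rows - r0 + 2L)] <- TRUE
  m
}

# 4-direction Crofton perimeter via the 16-configuration 2x2 lookup table
# (line-intercept counts in the two axis and two diagonal directions).
# Configuration code at (i,j) of the zero-padded mask:
#   1*m[i,j] + 4*m[i,j-1] + 2*m[i-1,j] + 8*m[i-1,j-1]
crofton_perimeter_px <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  g <- matrix(0L, h + 2L, w + 2L)
  g[2:(h + 1L), 2:(w + 1L)] <- mask
  cur <- g[2:(h + 2L), 2:(w + 2L)]
  lef <- g[2:(h + 2L), 1:(w + 1L)]
  up  <- g[1:(h + 1L), 2:(w + 2L)]
  upl <- g[1:(h + 1L), 1:(w + 1L)]
  cfg <- cur + 4L * lef + 2L * up + 8L * upl
  hist16 <- tabulate(cfg + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs * hist16)
}

# total length of the half-level (marching-squares) iso-contour of the mask
contour_perimeter_px <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  g <- matrix(0, h + 2L, w + 2L)
  g[2:(h + 1L), 2:(w + 1L)] <- mask
  cl <- grDevices::contourLines(x = seq_len(h + 2L), y = seq_len(w + 2L),
                                z = g, levels = 0.5)
  sum(vapply(cl, function(cc)
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), numeric(1)))
}

# exposed pixel-edge count (naive boundary length, strong positive bias on
# oblique boundaries; kept for sensitivity analysis)
boundary_perimeter_px <- function(mask) {
  n <- sum(mask)
  hadj <- sum(mask[-nrow(mask), ] & mask[-1, ])
  vadj <- sum(mask[, -ncol(mask)] & mask[, -1])
  4 * n - 2 * (hadj + vadj)
}

#' Estimate the perimeter of a binary pixel mask in micrometres
#'
#' The default `"dual"` estimator averages two classical estimators with
#' opposite-signed bias: the 4-direction Crofton line-intercept estimator
#' (accurate on curved digital shapes but systematically short on
#' corner-rich, axis-aligned ones -- about -5% analytically on a square)
#' and the half-level marching-squares contour length (near-exact on
#' axis-aligned shapes but about +7% on oblique/curved boundaries). Their
#' mean stays within 5% of the analytic perimeter on both the square and
#' disc reference shapes. Each component estimator is also available
#' directly, as is naive boundary-edge counting.
#'
#' @param mask Logical matrix (or coercible).
#' @param microns_per_pixel Physical pixel size.
#' @param method `"dual"`, `"crofton"`, `"contour"` or `"boundary"`.
#' @param warn_empty Warn (and return 0) on an empty mask.
#' @return Perimeter in micrometres.
#' @export
estimate_perimeter <- function(mask, microns_per_pixel,
                               method = c("dual", "crofton", "contour",
                                          "boundary"),
                               warn_empty = TRUE) {
  method <- match.arg(method)
  stopifnot(is.matrix(mask), microns_per_pixel > 0)
  mask <- mask != 0
  if (!any(mask)) {
    if (warn_empty) warning("empty mask: perimeter 0")
    return(0)
  }
  px <- switch(method,
    dual = (crofton_perimeter_px(mask) + contour_perimeter_px(mask)) / 2,
    crofton = crofton_perimeter_px(mask),
    contour = contour_perimeter_px(mask),
    boundary = boundary_perimeter_px(mask))
  px * microns_per_pixel
}

#' Fill per-cell morphometrics on a segmentation result
#'
#' For every cell: process area `|process_mask| * mpp^2`, process perimeter
#' via [estimate_perimeter()] on the assigned mask, and total Iba1 area of
#' the cell (the assigned mask is inclusive of soma-overlapping Iba1, so
#' the two areas coincide at the cell level; they differ at region level,
#' where total Iba1 also counts non-process signal). Only nucleus-attached
#' Iba1 contributes to the per-cell process metrics.
#'
#' @param seg A [assign_processes()] result.
#' @param perimeter_method Passed to [estimate_perimeter()].
#' @return `seg` with cell metrics filled.
#' @export
measure_cells <- function(seg, perimeter_method = "dual") {
  stopifnot(inherits(seg, "segmentation_result"))
  mpp <- seg$microns_per_pixel
  h <- seg$dim[1]; w <- seg$dim[2]
  seg$cells <- lapply(seg$cells, function(cell) {
    n <- length(cell$process_idx)
    cell$process_area_um2 <- n * mpp^2
    cell$total_iba1_area_um2 <- n * mpp^2
    if (n == 0) {
      cell$process_perimeter_um <- 0
    } else {
      cell$process_perimeter_um <-
        estimate_perimeter(mask_from_idx(cell$process_idx, h, w), mpp,
                           method = perimeter_method, warn_empty = FALSE)
    }
    cell
  })
  seg$perimeter_method <- perimeter_method
  seg
}

#' Summarise a segmented field into per-region morphometry
#'
#' The four reported metrics: nuclei per mm^2 of imaged area; total Iba1
#' immunoreactive area (cell-attached plus non-process) divided by the
#' nucleus count; mean per-cell process area; mean per-cell process
#' perimeter. Per-nucleus quantities are `NA` when no nucleus was found.
#'
#' @param seg A measured segmentation ([measure_cells()]).
#' @param image The source [calibrated_image()] (supplies region label and
#'   imaged area).
#' @return One-row data.frame of class `region_morphometry`.
#' @export
summarize_region <- function(seg, image) {
  stopifnot(inherits(seg, "segmentation_result"),
            inherits(image, "calibrated_image"))
  mpp <- seg$microns_per_pixel
  area_mm2 <- prod(seg$dim) * mpp^2 / 1e6
  if (area_mm2 <= 0) stop("zero imaged area")
  n <- length(seg$cells)
  cell_area <- vapply(seg$cells, `[[`, 0, "process_area_um2")
  if (n > 0 && any(is.na(cell_area)))
    stop("cells not measured; run measure_cells() first")
  total_iba1_um2 <- seg$n_iba1_px * mpp^2
  out <- data.frame(
    region = image$region,
    imaged_area_mm2 = area_mm2,
    n_nuclei = n,
    cells_per_mm2 = n / area_mm2,
    total_iba1_area_per_nucleus_um2 = if (n > 0) total_iba1_um2 / n else NA,
    process_area_per_nucleus_um2 = if (n > 0) mean(cell_area) else NA,
    process_perimeter_per_nucleus_um =
      if (n > 0) mean(vapply(seg$cells, `[[`, 0, "process_perimeter_um"))
      else NA,
    non_process_iba1_area_um2 = length(seg$non_process_idx) * mpp^2,
    stringsAsFactors = FALSE)
  class(out) <- c("region_morphometry", class(out))
  out
}
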