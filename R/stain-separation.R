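# Colour deconvolution of the purple/brown dual stain. Chromogen
# absorbances combine linearly in optical-density space (Beer-Lambert), so
# per-pixel stain concentrations are the least-squares solution of a 3 x 2
# linear system.

#' Convert 8-bit RGB transmitted light to optical density
#'
#' `OD_c = -log10((pixel_c + eps) / (i0 + eps))` per channel. The small
#' `eps` avoids `log(0)` for saturated dark pixels and is added to both
#' numerator and reference so a pixel at full transmission maps to exactly
#' zero OD.
#'
#' @param image A [calibrated_image()] or an H x W x 3 array in `[0, 255]`.
#' @param i0 Incident light intensity (default 255).
#' @param eps Small positive constant (default 1/255).
#' @return H x W x 3 numeric array of optical densities.
#' @export
rgb_to_od <- function(image, i0 = 255, eps = 1 / 255) {
  stopifnot(i0 > 0, eps > 0)
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  -log10((px + eps) / (i0 + eps))
}

#' @rdname rgb_to_od
#' @param od H x W x 3 optical-density array.
#' @export
od_to_rgb <- function(od, i0 = 255) {
  pmin(pmax(round(i0 * 10^-od), 0), 255)
}

#' Unmix a two-stain optical-density image into per-stain maps
#'
#' Solves, per pixel, the least-squares decomposition of the 3-vector OD
#' onto the two stain vectors. Negative concentrations are clipped to zero;
#' the per-pixel Euclidean norm of the reconstruction error after clipping
#' (unexplained plus clipped mass) is reported as `residual_od`.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param stain_vectors 3 x 2 matrix of unit stain vectors (columns
#'   `iba1`, `pu1`); near-collinear vectors (condition number > 1e6) are an
#'   error.
#' @param microns_per_pixel Carried through to the output.
#' @return Object of class `stain_maps`: list of H x W matrices `iba1_od`,
#'   `pu1_od`, `residual_od`, plus `microns_per_pixel`.
#' @export
unmix_stains <- function(od, stain_vectors = default_stain_vectors(),
                         microns_per_pixel = NULL) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3)
  v <- stain_vectors
  if (!is.matrix(v) || !all(dim(v) == c(3, 2)))
    stop("stain_vectors must be 3 x 2")
  kp <- kappa(v, exact = TRUE)
  if (!is.finite(kp) || kp > 1e6)
    stop(sprintf(
      "stain vectors are near-collinear (condition number %.3g > 1e6); %s",
      kp, "unmixing is ill-posed"))
  h <- dim(od)[1]; w <- dim(od)[2]
  flat <- matrix(od, h * w, 3)
  conc <- flat %*% v %*% solve(crossprod(v))   # N x 2 least squares
  conc_clip <- pmax(conc, 0)
  resid <- flat - conc_clip %*% t(v)
  structure(list(
    iba1_od = matrix(conc_clip[, 1], h, w),
    pu1_od = matrix(conc_clip[, 2], h, w),
    residual_od = matrix(sqrt(rowSums(resid^2)), h, w),
    microns_per_pixel = microns_per_pixel
  ), class = "stain_maps")
}

#' Threshold a scalar map into a binary mask
#'
#' Default is Otsu's method (maximising between-class variance over 256
#' candidate levels); a fixed threshold is supported for reproducibility.
#' The chosen threshold is recorded on the returned mask. A constant map
#' under Otsu yields an empty mask with a warning, not an error.
#'
#' @param map H x W numeric matrix (e.g. one channel of a `stain_maps`).
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @param microns_per_pixel Physical scale carried on the mask.
#' @return Object of class `binary_mask`: list with logical `mask`,
#'   `microns_per_pixel`, `threshold`, `method`.
#' @export
threshold_channel <- function(map, method = c("otsu", "fixed"), value = NULL,
                              microns_per_pixel = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(map), all(is.finite(map)))
  if (method == "fixed") {
    if (is.null(value)) stop("fixed thresholding requires `value`")
    th <- value
  } else {
    rg <- range(map)
    if (diff(rg) == 0) {
      warning("constant map: Otsu threshold undefined, returning empty mask")
      th <- rg[2]          # mask = map > max  ->  empty
    } else {
      th <- EBImage::otsu(EBImage::Image(map), range = rg, levels = 256)
    }
  }
  structure(list(mask = map > th,
                 microns_per_pixel = microns_per_pixel,
                 threshold = th, method = method),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px (threshold %.4g, %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold, x$method))
  invisible(x)
}
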