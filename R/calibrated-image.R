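#' Calibrated RGB brightfield image
#'
#' Thin container tying an 8-bit RGB pixel grid to its physical scale and
#' anatomical region, the unit every downstream step consumes.
#'
#' @param pixels H x W x 3 numeric/integer array with values in `[0, 255]`.
#' @param microns_per_pixel Physical pixel size (> 0, finite).
#' @param region One of `"cortex"`, `"hippocampus"`, `"striatum"`,
#'   `"cerebellum"`, `"other"`.
#' @param animal Optional list of animal metadata (id, genotype, age, gender).
#'
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, microns_per_pixel,
                             region = c("cortex", "hippocampus", "striatum",
                                        "cerebellum", "other"),
                             animal = NULL) {
  region <- match.arg(region)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 1, dim(pixels)[2] >= 1,
            is.finite(microns_per_pixel), microns_per_pixel > 0)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 region = region, animal = animal),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px @ %.3g um/px, region: %s\n",
              d[1], d[2], x$microns_per_pixel, x$region))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Read / write calibrated images as 8-bit RGB PNG
#'
#' PNG carries no physical scale, so `read_image()` takes the scale and
#' region explicitly (they travel in the cohort manifest).
#'
#' @param image A `calibrated_image`.
#' @param path File path.
#' @param microns_per_pixel,region,animal Passed to [calibrated_image()].
#' @return `write_image()` returns `path` invisibly; `read_image()` a
#'   `calibrated_image`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, microns_per_pixel, region = "other",
                       animal = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  calibrated_image(round(px * 255), microns_per_pixel, region, animal)
}

#' Write an integer label mask as a 16-bit grayscale PNG
#'
#' @param labels Integer matrix, 0 = background.
#' @param path File path.
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  png::writePNG(labels / 65535, target = path)
  invisible(path)
}
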