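#' Segment one calibrated dual-stain image end to end
#'
#' Runs colour deconvolution ([rgb_to_od()], [unmix_stains()]), per-channel
#' thresholding ([threshold_channel()]), nucleus detection
#' ([detect_nuclei()]) and process assignment ([assign_processes()]), then
#' fills per-cell morphometrics ([measure_cells()]).
#'
#' @param image A [calibrated_image()].
#' @param stain_vectors 3 x 2 stain matrix, see [default_stain_vectors()].
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_thresholds Named list `list(iba1 =, pu1 =)` when
#'   `threshold_method = "fixed"`.
#' @param radius_um Contiguity radius (default 2 um).
#' @param nucleus_area_um2 Length-2 nucleus area window in um^2.
#' @param perimeter_method Passed to [estimate_perimeter()].
#' @return A measured `segmentation_result`.
#' @export
segment_image <- function(image,
                          stain_vectors = default_stain_vectors(),
                          threshold_method = c("otsu", "fixed"),
                          fixed_thresholds = NULL,
                          radius_um = 2.0,
                          nucleus_area_um2 = c(5, 200),
                          perimeter_method = "dual") {
  stopifnot(inherits(image, "calibrated_image"))
  threshold_method <- match.arg(threshold_method)
  od <- rgb_to_od(image)
  maps <- unmix_stains(od, stain_vectors,
                       microns_per_pixel = image$microns_per_pixel)
  th <- function(map, which) {
    if (threshold_method == "fixed")
      threshold_channel(map, "fixed", value = fixed_thresholds[[which]],
                        microns_per_pixel = image$microns_per_pixel)
    else
      threshold_channel(map, "otsu",
                        microns_per_pixel = image$microns_per_pixel)
  }
  iba1_mask <- th(maps$iba1_od, "iba1")
  pu1_mask <- th(maps$pu1_od, "pu1")
  nuclei <- detect_nuclei(pu1_mask, nucleus_area_um2[1], nucleus_area_um2[2])
  seg <- assign_processes(iba1_mask, nuclei, radius_um = radius_um)
  seg$params$pu1_threshold <- pu1_mask$threshold
  measure_cells(seg, perimeter_method = perimeter_method)
}

#' Per-region morphometry of one image
#'
#' @inheritParams segment_image
#' @param ... Passed to [segment_image()].
#' @return One-row data.frame, see [summarize_region()].
#' @export
region_morphometry <- function(image, ...) {
  summarize_region(segment_image(image, ...), image)
}

#' Run the full imaging pipeline over a synthetic cohort
#'
#' Segments every animal x region image and returns the animal-level table
#' that the statistical analysis consumes (one row per animal x region).
#'
#' @param cohort A [generate_cohort()] result rendered with images.
#' @param ... Passed to [segment_image()].
#' @return data.frame with columns `animal_id`, `genotype`, `age`,
#'   `gender`, `region`, `n_nuclei`, `cells_per_mm2`,
#'   `iba1_area_per_nucleus_um2`, `process_area_per_nucleus_um2`,
#'   `process_perimeter_per_nucleus_um`, `non_process_iba1_area_um2`.
#' @export
cohort_morphometry <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$animals, function(an) {
    do.call(rbind, lapply(names(an$regions), function(reg) {
      img <- an$regions[[reg]]$image
      if (is.null(img))
        stop("cohort was generated without rendered images; ",
             "use ground_truth_morphometry() or render = \"image\"")
      rm <- region_morphometry(img, ...)
      data.frame(
        animal_id = an$animal_id, genotype = an$genotype, age = an$age,
        gender = an$gender, region = reg,
        n_nuclei = rm$n_nuclei,
        cells_per_mm2 = rm$cells_per_mm2,
        iba1_area_per_nucleus_um2 = rm$total_iba1_area_per_nucleus_um2,
        process_area_per_nucleus_um2 = rm$process_area_per_nucleus_um2,
        process_perimeter_per_nucleus_um = rm$process_perimeter_per_nucleus_um,
        non_process_iba1_area_um2 = rm$non_process_iba1_area_um2,
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
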