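#' Generate a synthetic cohort of animals with per-region images
#'
#' Expands a [cohort_design()] into one animal per design slot (genotype x
#' age cell, `n_per_cell` animals each, genders interleaved within the
#' cell), derives a deterministic per-animal-region seed from the design
#' seed, applies the design's factor-level multipliers to each animal's
#' scene parameters, and renders one field per region. Cohort size mirrors
#' the study scale of roughly five mice per genotype/age/gender group.
#'
#' @param design A [cohort_design()].
#' @param base_params [synth_params()] used for every animal before effect
#'   multipliers are applied. Regions named `"cerebellum"` switch to the
#'   amoeboid morphology class (the cerebellar phenotype).
#' @param render `"image"` renders full RGB fields; `"masks"` skips
#'   rendering (ground truth only), for large replicate studies.
#' @return An object of class `cohort`: list with `animals` (each holding
#'   id, factors, and per-region `image` + `ground_truth` + `params`),
#'   `manifest` (one data-frame row per animal x region) and the `design`.
#' @export
generate_cohort <- function(design, base_params = synth_params(),
                            render = c("image", "masks")) {
  stopifnot(inherits(design, "cohort_design"))
  render <- match.arg(render)
  validate_synth_params(base_params)

  grid <- expand.grid(genotype = design$genotypes, age = design$ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  animals <- list()
  aid <- 0L
  for (g in seq_len(nrow(grid))) {
    for (j in seq_len(design$n_per_cell)) {
      aid <- aid + 1L
      animals[[aid]] <- list(
        animal_id = sprintf("A%03d", aid),
        genotype = grid$genotype[g],
        age = grid$age[g],
        gender = design$genders[(j - 1L) %% length(design$genders) + 1L]
      )
    }
  }
  n_animals <- length(animals)
  set.seed(design$seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      n_animals * length(design$regions))

  manifest <- NULL
  k <- 0L
  for (i in seq_len(n_animals)) {
    an <- animals[[i]]
    an$regions <- list()
    for (reg in design$regions) {
      k <- k + 1L
      p <- animal_params(base_params, design, an, reg, seeds[k])
      out <- generate_microglia_image(p, render = (render == "image"))
      if (!is.null(out$image)) {
        out$image$region <- if (reg %in% c("cortex", "hippocampus",
                                           "striatum", "cerebellum")) reg
                            else "other"
        out$image$animal <- an[c("animal_id", "genotype", "age", "gender")]
      }
      an$regions[[reg]] <- list(image = out$image,
                                ground_truth = out$ground_truth,
                                params = p)
      manifest <- rbind(manifest, data.frame(
        animal_id = an$animal_id, genotype = an$genotype, age = an$age,
        gender = an$gender, region = reg, seed = seeds[k],
        n_cells_true = out$ground_truth$n_cells,
        stringsAsFactors = FALSE))
    }
    animals[[i]] <- an
  }
  structure(list(animals = animals, manifest = manifest, design = design),
            class = "cohort")
}

# per-animal scene parameters: base, switched to the amoeboid class for the
# cerebellum, then scaled by the product of the matching factor-level
# multipliers
animal_params <- function(base, design, animal, region, seed) {
  p <- base
  if (identical(region, "cerebellum") &&
      base$morphology_class != "amoeboid") {
    p <- synth_params(n_cells = base$n_cells, morphology_class = "amoeboid",
                      stain_vectors = base$stain_vectors,
                      background_od = base$background_od,
                      noise_sd = base$noise_sd,
                      microns_per_pixel = base$microns_per_pixel,
                      image_size_px = base$image_size_px)
  }
  for (par in names(design$effects)) {
    m <- 1
    for (fac in names(design$effects[[par]])) {
      lv <- animal[[fac]]
      mv <- design$effects[[par]][[fac]]
      if (!is.null(lv) && lv %in% names(mv)) m <- m * mv[[lv]]
    }
    p[[par]] <- if (par == "n_cells") max(0L, as.integer(round(p[[par]] * m)))
                else p[[par]] * m
  }
  p$seed <- as.integer(seed)
  validate_synth_params(p)
  p
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animals x %d region(s); design %s x %s\n",
              length(x$animals), length(x$design$regions),
              paste(x$design$genotypes, collapse = "/"),
              paste(x$design$ages, collapse = "/")))
  invisible(x)
}

#' Animal-level morphometry table straight from ground truth
#'
#' Bypasses rendering and segmentation: summarises each animal x region
#' directly from the generator's per-cell masks. Schema matches
#' [cohort_morphometry()] so the same statistical analysis applies.
#'
#' @param cohort A [generate_cohort()] result.
#' @return data.frame, one row per animal x region.
#' @export
ground_truth_morphometry <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$animals, function(an) {
    do.call(rbind, lapply(names(an$regions), function(reg) {
      gt <- an$regions[[reg]]$ground_truth
      p <- an$regions[[reg]]$params
      area_mm2 <- prod(p$image_size_px) * p$microns_per_pixel^2 / 1e6
      n <- gt$n_cells
      data.frame(
        animal_id = an$animal_id, genotype = an$genotype, age = an$age,
        gender = an$gender, region = reg,
        n_nuclei = n,
        cells_per_mm2 = n / area_mm2,
        iba1_area_per_nucleus_um2 =
          if (n > 0) mean(vapply(gt$cells, `[[`, 0, "iba1_area_um2")) else NA,
        process_area_per_nucleus_um2 =
          if (n > 0) mean(vapply(gt$cells, `[[`, 0, "process_area_um2")) else NA,
        process_perimeter_per_nucleus_um =
          if (n > 0) mean(vapply(gt$cells, `[[`, 0, "process_perimeter_um"))
          else NA,
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
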