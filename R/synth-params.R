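#' Parameters for the synthetic dual-stain histology generator
#'
#' Bundles everything [generate_microglia_image()] needs to render one
#' calibrated field of Iba1(purple)/Pu.1(brown) microglia. Per-class
#' defaults describe a ramified (cortical-like) or amoeboid
#' (cerebellar-like) morphology; any field can be overridden.
#'
#' @param n_cells Number of cells to attempt to place (>= 0).
#' @param soma_radius_um Soma radius in micrometres.
#' @param n_processes_per_cell Number of processes sprouting from each soma.
#' @param process_length_um Length-2 numeric `c(mean, sd)` of the per-process
#'   length distribution (micrometres, normal truncated at 1 um).
#' @param process_thickness_um Full process thickness in micrometres.
#' @param morphology_class `"ramified"` (long thin branches) or `"amoeboid"`
#'   (enlarged soma, short stubby processes).
#' @param stain_vectors 3 x 2 matrix of unit optical-density stain vectors,
#'   columns `iba1` and `pu1`; see [default_stain_vectors()].
#' @param background_od Neutral background optical density (>= 0).
#' @param noise_sd Gaussian pixel noise s.d. in OD space (>= 0).
#' @param microns_per_pixel Physical pixel size (> 0). Default 0.5 um/px, a
#'   typical 20x whole-slide scan.
#' @param image_size_px Integer `c(height, width)` of the rendered field.
#' @param min_separation_um Minimum soma centre-to-centre distance during
#'   placement. `NULL` (default) only forbids soma overlap
#'   (`2 * soma_radius_um` plus a small gap); larger values produce
#'   well-separated cells whose process arbours cannot touch (process
#'   length is truncated at mean + 3 sd, bounding each cell's reach).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_cells = 12,
                         soma_radius_um = NULL,
                         n_processes_per_cell = NULL,
                         process_length_um = NULL,
                         process_thickness_um = NULL,
                         morphology_class = c("ramified", "amoeboid"),
                         stain_vectors = default_stain_vectors(),
                         background_od = 0.03,
                         noise_sd = 0.01,
                         microns_per_pixel = 0.5,
                         image_size_px = c(400L, 400L),
                         min_separation_um = NULL,
                         seed = 1L) {
  morphology_class <- match.arg(morphology_class)
  defaults <- switch(morphology_class,
    ramified = list(soma_radius_um = 3.5, n_processes_per_cell = 4,
                    process_length_um = c(15, 4), process_thickness_um = 1.0),
    amoeboid = list(soma_radius_um = 4.5, n_processes_per_cell = 2,
                    process_length_um = c(5, 1.5), process_thickness_um = 1.4))
  if (is.null(soma_radius_um)) soma_radius_um <- defaults$soma_radius_um
  if (is.null(n_processes_per_cell))
    n_processes_per_cell <- defaults$n_processes_per_cell
  if (is.null(process_length_um))
    process_length_um <- defaults$process_length_um
  if (is.null(process_thickness_um))
    process_thickness_um <- defaults$process_thickness_um

  p <- structure(list(
    n_cells = as.integer(n_cells),
    soma_radius_um = soma_radius_um,
    n_processes_per_cell = as.integer(n_processes_per_cell),
    process_length_um = process_length_um,
    process_thickness_um = process_thickness_um,
    morphology_class = morphology_class,
    stain_vectors = stain_vectors,
    background_od = background_od,
    noise_sd = noise_sd,
    microns_per_pixel = microns_per_pixel,
    image_size_px = as.integer(image_size_px),
    min_separation_um = min_separation_um,
    seed = as.integer(seed)
  ), class = "synth_params")
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  stopifnot(
    p$n_cells >= 0,
    p$soma_radius_um > 0,
    p$n_processes_per_cell >= 0,
    length(p$process_length_um) == 2, p$process_length_um[1] > 0,
    p$process_length_um[2] >= 0,
    p$process_thickness_um > 0,
    p$background_od >= 0, p$noise_sd >= 0,
    p$microns_per_pixel > 0, is.finite(p$microns_per_pixel),
    length(p$image_size_px) == 2, all(p$image_size_px >= 1),
    is.null(p$min_separation_um) || p$min_separation_um > 0
  )
  v <- p$stain_vectors
  if (!is.matrix(v) || !all(dim(v) == c(3, 2)))
    stop("stain_vectors must be a 3 x 2 matrix (columns iba1, pu1)")
  if (any(abs(sqrt(colSums(v^2)) - 1) > 1e-6))
    stop("stain vectors must have unit norm")
  if (kappa(v) > 1e6)
    stop("stain vectors are (near-)collinear")
  invisible(p)
}

#' Default optical-density stain vectors for the purple/brown stain pair
#'
#' The purple (Iba1, alkaline-phosphatase-type chromogen) channel uses the
#' classical haematoxylin-like blue-purple absorbance vector and the brown
#' (Pu.1) channel the DAB vector of Ruifrok & Johnston colour deconvolution,
#' both normalised to unit length. Stain vectors are instrument- and
#' chromogen-dependent; calibrate and override for real slides.
#'
#' @return 3 x 2 numeric matrix with columns `iba1` and `pu1` (rows R, G, B).
#' @export
default_stain_vectors <- function() {
  v <- cbind(iba1 = c(0.650, 0.704, 0.286),
             pu1  = c(0.268, 0.570, 0.776))
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Factorial cohort design for synthetic morphometry studies
#'
#' Describes a genotype x age cohort (genders interleaved within each
#' design cell) and the multiplicative effects each factor level applies to
#' the scene parameters of individual animals.
#'
#' @param genotypes Character subset of `c("WT", "Het", "KO")`.
#' @param ages Character age labels, e.g. `c("2mo", "2yr")`.
#' @param genders Character subset of `c("M", "F")`; assigned alternately
#'   within each genotype x age cell (near-balanced split).
#' @param n_per_cell Animals per genotype x age cell (>= 2 so downstream
#'   ANOVA has residual degrees of freedom).
#' @param effects Named list of per-parameter, per-factor level multipliers
#'   applied to each animal's [synth_params()]. Targets: `process_thickness_um`,
#'   `process_length_um`, `n_cells`. Example:
#'   `list(process_thickness_um = list(genotype = c(WT = 1, KO = 0.7)))`.
#'   Omitted levels default to 1; all multipliers must be > 0.
#' @param regions Character vector of brain regions imaged per animal.
#'   `"cerebellum"` is rendered with the amoeboid morphology class.
#' @param seed Integer design seed; per-animal seeds are derived from it
#'   deterministically.
#'
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(genotypes = c("WT", "KO"),
                          ages = c("2mo", "2yr"),
                          genders = c("M", "F"),
                          n_per_cell = 9,
                          effects = list(),
                          regions = "cortex",
                          seed = 1L) {
  if (length(genotypes) == 0 || length(ages) == 0 || length(genders) == 0 ||
      length(regions) == 0)
    stop("genotypes, ages, genders and regions must all be non-empty")
  stopifnot(all(genotypes %in% c("WT", "Het", "KO")),
            all(genders %in% c("M", "F")),
            n_per_cell >= 2)
  allowed <- c("process_thickness_um", "process_length_um", "n_cells")
  if (length(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% allowed))
      stop("effects must be named after: ", paste(allowed, collapse = ", "))
    mults <- unlist(effects)
    if (any(!is.finite(mults)) || any(mults <= 0))
      stop("all effect multipliers must be finite and > 0")
  }
  structure(list(genotypes = genotypes, ages = ages, genders = genders,
                 n_per_cell = as.integer(n_per_cell), effects = effects,
                 regions = regions, seed = as.integer(seed)),
            class = "cohort_design")
}
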