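---
title: "Methods: dual-stain microglial morphometry with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-stain microglial morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Brightfield dual immunohistochemistry stains the microglial cytosol
(Iba1, a purple chromogen) and the microglial nucleus (Pu.1, a brown
DAB-type chromogen). The quantity of interest is per-cell: how much Iba1
signal belongs to each nucleus, how large and how convoluted the process
arbour is, and how many cells populate a region. The attribution rule is
geometric: all contiguous Iba1 immunoreactivity within a 2 µm radius of a
Pu.1-positive nucleus is that cell's process mask; Iba1 not attributable
to any nucleus is non-process signal. Four metrics summarise a region:
nuclei per mm², total Iba1 area per nucleus, process area per nucleus and
process perimeter per nucleus.

## Optical model and stain separation

Chromogen absorbances combine linearly in optical-density space
(Beer–Lambert): `OD_c = -log10((I_c + eps) / (I0 + eps))` per channel,
with `I0 = 255` and `eps = 1/255` so a fully transmitting pixel maps to
exactly zero OD. Each pixel's 3-vector OD is decomposed by least squares
onto two unit stain vectors; negative concentrations are clipped at zero
and the residual norm after clipping is reported per pixel. Near-collinear
stain vectors (condition number above 1e6) are rejected with a diagnostic,
since the decomposition is then ill-posed.

The shipped default vectors are the classical colour-deconvolution pair —
haematoxylin-like blue-purple `(0.65, 0.70, 0.29)` for the
alkaline-phosphatase-type purple chromogen and DAB `(0.27, 0.57, 0.78)`
for the brown — normalised to unit length. Stain vectors are instrument-
and chromogen-dependent; for real slides they should be calibrated on
single-stain controls and passed explicitly.

Thresholding defaults to Otsu per channel (the original study's fixed
"minimum threshold" value is not published); a fixed threshold is
available for reproducibility, and the chosen value is recorded on the
mask. Only a global per-image threshold is implemented; the original
software's rule (global vs adaptive) is not described, and a global rule
is the simplest defensible reading.

## Segmentation decisions

* **Connectivity** is 8-connected for both stains: 1-px-wide diagonal
  process segments must remain contiguous. The labelling is delegated to
  `EBImage::bwlabel` (4-connected) followed by a union-find merge over
  diagonal label contacts, and is oracle-tested against a flood fill.
* **The 2 µm radius is inclusive** (`distance <= 2.0 um`), scale-aware via
  the image's microns-per-pixel. The rule's source states the radius but
  not inclusivity; inclusive was chosen once and is tested at exactly
  4 px = 2.0 µm.
* **Shared components.** A single Iba1 component can lie within radius of
  two or more nuclei; how the original software resolved this is not
  documented. We partition such components by within-component geodesic
  distance: component pixels within radius of a nucleus form that
  nucleus's seed set (a pixel within radius of several nuclei seeds for
  the Euclidean-nearest, ties to the lower id), and a multi-source BFS
  over the 8-neighbour pixel graph labels the rest, same-level ties again
  to the lower id. This avoids double counting — one pixel contributes to
  exactly one cell — and makes the partition identity (cell masks plus
  non-process mask tile the Iba1 mask, pixel-exactly) an invariant the
  code asserts on every run.
* **Nucleus area window** defaults to 5–200 µm², bracketing plausible
  microglial nuclei at 0.5 µm/px; merged nuclei are not split (no
  watershed), which matters only at densities beyond those simulated.

## Perimeter estimation

No single cheap digital estimator is uniformly within 5 % of continuous
perimeters. The 4-direction Crofton line-intercept estimator (16-entry
2×2-configuration lookup table) is excellent on curved shapes (+1.6 % on
a radius-20 px disc) but analytically short on axis-aligned corner-rich
shapes: the mean width of a square over the four fixed directions is
0.948 of its π-averaged width, so a 20×20 px square comes out ≈ −6.6 %.
The half-level marching-squares contour length behaves oppositely:
−1.5 % on the square, +7.2 % on the disc (staircase overestimation of
oblique boundaries). The default `"dual"` estimator is their mean, whose
component biases cancel to −4.0 % / +4.4 % on those two references — the
only estimator of the four shipped (`dual`, `crofton`, `contour`,
`boundary`) that meets the 5 % target on both. The estimator choice is
recorded on the segmentation result; `boundary` (exposed-edge counting,
≈ +27 % on discs) exists for sensitivity analysis only.

Per-nucleus process metrics are **means over cells** (equivalent to
region totals divided by counts when every nucleus yields a cell, which
holds in the simulated scenes); "total Iba1 area per nucleus" is the
region-total Iba1 area — including non-process signal — divided by the
nucleus count, which is why it is reported alongside, and is never
smaller than, the nucleus-attached process area.

## The synthetic-histology generator

The generator is the validation instrument: it renders scenes whose
per-cell masks, areas and perimeters are known exactly, so every pipeline
stage can be scored pixel-wise.

* **Scene.** Somata are discs (default radius 3.5 µm) placed by rejection
  sampling with non-overlap enforced; nuclei are concentric discs at 0.65
  of the soma radius. Each cell sprouts `n_processes_per_cell` (default 4)
  meandering polylines — 0.5 px steps with Gaussian direction jitter —
  of normal length (default 15 ± 4 µm, truncated at 1 µm and at
  mean + 3 sd to bound each cell's reach) and configured thickness
  (default 1 µm). Rasterisation tests pixel centres against the continuous
  capsule around the path, which keeps pixel counting an unbiased area
  estimator and makes multiplicative thickness effects recoverable from
  masks. A cerebellar "amoeboid" class (larger soma, two short thick
  stubs) mirrors the visibly less ramified morphology of that region.
* **Rendering.** Concentrations (0.8 Iba1 on soma+processes, 0.9 Pu.1 on
  nuclei) multiply the stain vectors in OD space; a neutral background OD
  (default 0.03) and i.i.d. Gaussian OD noise (default sd 0.01) are added;
  transmitted RGB is `255·10^-OD`, rounded to 8 bits. Noise is the one
  free choice — slide-to-slide staining variability is not documented
  anywhere usable — and Gaussian-in-OD is the conventional first-order
  model.
* **Ground truth.** Per cell: nucleus mask, full attached Iba1 mask
  (soma-inclusive — this is what the segmenter's inclusive process mask
  recovers), and the branch-only process mask. The soma-inclusive area
  carries the accuracy comparisons; the branch-only area is the quantity
  a process-thickness multiplier scales (soma area is thickness-
  invariant), so it carries the effect-fidelity checks. A thickness
  multiplier moves area but barely moves perimeter (perimeter tracks
  length, not width) — length or cell-count multipliers are the right
  dials for those metrics.
* **Cohorts.** A factorial design (genotypes × ages, genders interleaved
  within each cell, about nine animals per genotype×age cell) derives one
  deterministic seed per animal×region from the design seed and applies
  per-factor-level multiplicative effects to thickness, length or cell
  count. Everything is a pure function of (parameters, seed).

What the generator does **not** emulate: microglial clustering, uneven
staining across a slide, tissue folds and edge artefacts, chromatic
aberration, anisotropic point-spread, or biologically realistic arbour
topology (no secondary branching). Passing the validation suite therefore
shows the algorithm is correct under its geometric assumptions — not that
those assumptions hold on any particular scanner's output.

## Statistical analysis

The cohort table (one row per animal×region) is analysed per metric by a
two-way factorial ANOVA with interaction, sum-to-zero contrasts. Balanced
designs use the classical decomposition; unbalanced designs use Type-III
sums of squares (via `car::Anova`), matching the commercial software
family this analysis mirrors (the source never states its SS type; on
balanced data the two coincide, which is tested). Genders are pooled by
default; the stratified variant treats genotype×gender as a single
4-level factor, giving the F(3,28) structure on 36 animals. Tukey HSD
covers all group pairs from the pooled within-group variance; with two
groups it reduces to the pooled t-test (oracle-tested). Stars follow the
strict convention *P<0.05, **P<0.01, ***P<0.001, ****P<0.0001; exactly
0.05 is "ns". Zero residual variance yields NA p-values with a warning
rather than failure; missing responses are dropped listwise per metric.

A simplification: the biological finding is an age-dependent genotype
effect (thin processes in *young* KO only), but cohort effects here are
per-factor-level multipliers, so the validation cohort applies the
thinning to KO at both ages and tests the genotype main effect. Cell
means with per-cell multipliers would be needed to emulate the pure
interaction pattern.

## Genomics filter decisions

* FDR is Benjamini–Hochberg (the conventional default of the DE engine
  family involved; the source says only "FDR"), delegated to
  `p.adjust(method = "BH")` and oracle-tested against the literal step-up
  formula.
* "At least 30 % difference in fold change" is read symmetrically on the
  ratio scale (pass iff FC ≥ 1.3 or FC ≤ 1/1.3 ≈ 0.769); the alternative
  complement reading (FC ≤ 0.7) is a switch.
* The 4-TPM expression floor is strict (`> 4`) and averaged within the
  comparison at hand, not across the whole experiment.
* The TSS window is inclusive at exactly ±1000 bp, signed distances with
  negative = upstream; read support means ≥ 4 reads in at least one
  genotype; significance adds 2-fold (either direction) and IDR < 0.05
  (strict).
* qPCR: per-sample `2^-(Ct_gene - Ct_ref)`, then division by the
  reference-group mean, so the WT group averages exactly 1.
* Not implemented: the DE test itself (p-values are inputs), IDR
  computation, GO enrichment, and PCA-based outlier removal (the
  published description has no numeric rule to implement).

## Validation problem sizes

The suite validates at sizes chosen to keep a full run in minutes on one
core while leaving no estimate starved: 256×256 px fields with 8 cells
for the 36-animal pipeline cohorts; 20 noise-free 400×400 px fields with
4 cells at 60 µm separation for pixel-exact segmentation scoring ("well
separated" is the stated condition of that check — at default density
crossing arbours are legitimately split by the geodesic rule, which is
scored by its own oracle instead); 5 noise-free default-density fields
for area accuracy; 200 replicate mask-only cohorts for the null
rejection rate (scene size does not enter the ANOVA's null calibration);
and 50 × 1000-gene tables for the filter oracles. The null-rate
acceptance band was fixed a priori at the 99 % binomial band around 0.05.

## Known limitations

* Geodesic partition of shared components is a reasoned choice, not a
  reconstruction of the original software's (undocumented) behaviour; an
  implementation that double-counted shared components would report
  larger per-cell areas.
* Perimeter estimates inherit a few percent of shape-dependent bias;
  comparisons across groups are unaffected (same estimator throughout),
  absolute values should be quoted with that caveat.
* The generator's arbours are unbranched polylines; metrics sensitive to
  branching topology (e.g. Sholl profiles) are out of scope.
* Whole-slide concerns — tiling, pyramid levels, cross-slide colour
  normalisation — are not handled; inputs are single calibrated fields.
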