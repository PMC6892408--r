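Package: mgmorph
Title: Dual-Stain Brightfield Morphometry of Microglia with Synthetic
    Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative morphometry of microglia from dual-stain
    (Iba1/Pu.1) brightfield immunohistochemistry. Separates the two
    chromogens in optical-density space, detects Pu.1-positive nuclei,
    attributes contiguous Iba1 immunoreactivity to each nucleus within a
    2-micrometre contiguity radius, and summarises per-region cell density,
    Iba1 area, process area and process perimeter per nucleus. Includes a
    calibrated synthetic-histology generator with exact per-cell ground
    truth for end-to-end validation, two-way ANOVA with Tukey post hoc
    comparisons for cohort tables, and the threshold-based genomics filters
    used alongside the imaging assay (Benjamini-Hochberg adjustment,
    TPM/fold-change/FDR differential-expression rules, TSS-window ChIP peak
    filtering, and delta-delta-Ct qPCR normalisation).
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    car,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
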