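test_that("generator is a pure function of parameters and seed", {
  p <- synth_params(n_cells = 5, seed = 11, image_size_px = c(160L, 160L))
  a <- generate_microglia_image(p)
  b <- generate_microglia_image(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$ground_truth$label_mask, b$ground_truth$label_mask)

  tab1 <- generate_gene_stat_table(n_genes = 200, n_true_de = 20, seed = 5)
  tab2 <- generate_gene_stat_table(n_genes = 200, n_true_de = 20, seed = 5)
  expect_identical(tab1, tab2)
})

test_that("zero cells give a blank background and empty ground truth", {
  p <- synth_params(n_cells = 0, seed = 1, noise_sd = 0,
                    image_size_px = c(64L, 64L))
  out <- generate_microglia_image(p)
  expect_equal(out$ground_truth$n_cells, 0)
  expect_lte(length(unique(as.vector(out$image$pixels))), 3) # flat background
  expect_true(all(out$ground_truth$label_mask == 0L))
})

test_that("an image too small for one soma is an explicit failure", {
  p <- synth_params(n_cells = 3, soma_radius_um = 10,
                    image_size_px = c(20L, 20L), seed = 1)
  expect_error(generate_microglia_image(p), "too small")
})

test_that("recorded areas equal independent pixel recounts of the masks", {
  p <- synth_params(n_cells = 6, seed = 23, noise_sd = 0,
                    image_size_px = c(256L, 256L))
  gt <- generate_microglia_image(p)$ground_truth
  mpp <- p$microns_per_pixel
  expect_equal(gt$n_cells, 6)
  for (cell in gt$cells) {
    expect_equal(cell$iba1_area_um2, length(unique(cell$iba1_idx)) * mpp^2)
    expect_equal(cell$process_area_um2,
                 length(unique(cell$process_idx)) * mpp^2)
    expect_equal(cell$nucleus_area_um2, length(cell$nucleus_idx) * mpp^2)
    # processes exclude the soma; nucleus lies inside the soma
    expect_length(intersect(cell$process_idx, cell$nucleus_idx), 0)
    expect_true(all(cell$nucleus_idx %in% cell$iba1_idx))
  }
  # nucleus masks of distinct cells are disjoint
  all_nuc <- unlist(lapply(gt$cells, `[[`, "nucleus_idx"))
  expect_false(any(duplicated(all_nuc)))
  # label mask recount matches the recorded total
  expect_equal(gt$total_iba1_area_um2, sum(gt$label_mask > 0) * mpp^2)
})

test_that("mask-only rendering reproduces the rendered scene exactly", {
  p <- synth_params(n_cells = 4, seed = 9, image_size_px = c(128L, 128L))
  full <- generate_microglia_image(p, render = TRUE)
  fast <- generate_microglia_image(p, render = FALSE)
  expect_null(fast$image)
  expect_identical(full$ground_truth$label_mask, fast$ground_truth$label_mask)
})

test_that("cohort expansion gives one animal per design slot", {
  des <- cohort_design(n_per_cell = 9, seed = 3)
  bp <- synth_params(n_cells = 3, image_size_px = c(96L, 96L))
  coh <- generate_cohort(des, bp, render = "masks")
  expect_length(coh$animals, 36)          # 2 genotypes x 2 ages x 9
  expect_equal(nrow(coh$manifest), 36)
  expect_equal(as.vector(table(coh$manifest$genotype)), c(18, 18))
  # per-animal seeds are distinct and deterministic
  expect_false(any(duplicated(coh$manifest$seed)))
  coh2 <- generate_cohort(des, bp, render = "masks")
  expect_identical(coh$manifest, coh2$manifest)
  expect_error(cohort_design(genotypes = character(0)), "non-empty")
})

test_that("factor-level multipliers propagate to group means of ground truth", {
  des <- cohort_design(
    n_per_cell = 9, seed = 77,
    effects = list(process_thickness_um = list(genotype = c(WT = 1, KO = 0.7))))
  coh <- generate_cohort(des, synth_params(noise_sd = 0), render = "masks")
  tab <- ground_truth_morphometry(coh)
  m <- tapply(tab$process_area_per_nucleus_um2, tab$genotype, mean)
  expect_lt(abs(m[["KO"]] / m[["WT"]] - 0.7), 0.05 * 0.7)

  # null multipliers: groups statistically indistinguishable at this seed
  des0 <- cohort_design(n_per_cell = 9, seed = 78)
  coh0 <- generate_cohort(des0,
                          synth_params(n_cells = 8, noise_sd = 0,
                                       image_size_px = c(256L, 256L)),
                          render = "masks")
  tab0 <- ground_truth_morphometry(coh0)
  a <- two_way_anova(tab0, "genotype", "age", "process_area_per_nucleus_um2")
  expect_gt(min(a$effects$p_value), 0.05)
})

test_that("cell-count multipliers scale the cell-density morphometric", {
  des <- cohort_design(
    n_per_cell = 9, seed = 31,
    effects = list(n_cells = list(genotype = c(WT = 1, KO = 0.5))))
  coh <- generate_cohort(des,
                         synth_params(n_cells = 12, noise_sd = 0,
                                      image_size_px = c(300L, 300L)),
                         render = "masks")
  tab <- ground_truth_morphometry(coh)
  m <- tapply(tab$cells_per_mm2, tab$genotype, mean)
  expect_lt(abs(m[["KO"]] / m[["WT"]] - 0.5), 0.05 * 0.5)
})

test_that("gene table nulls are uniform and true DEGs respect the FC floor", {
  tab <- generate_gene_stat_table(n_genes = 2000, n_true_de = 0, seed = 4)
  frac <- mean(tab$p < 0.05)
  expect_lt(abs(frac - 0.05), 2.5 * sqrt(0.05 * 0.95 / 2000))

  tab2 <- generate_gene_stat_table(n_genes = 1000, n_true_de = 100,
                                   effect = c(1.5, 8), seed = 6)
  fc <- tab2$fold_change[tab2$true_de]
  expect_true(all(fc >= 1.5 | fc <= 1 / 1.5))
  expect_true(all(is.na(tab2$fdr)))
  expect_error(generate_gene_stat_table(n_genes = 10, n_true_de = 11))
})
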