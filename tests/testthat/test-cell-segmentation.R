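# build a binary_mask around a logical matrix at a given scale
bmask <- function(m, mpp = 0.5) {
  structure(list(mask = m, microns_per_pixel = mpp, threshold = 0.5,
                 method = "fixed"), class = "binary_mask")
}
disc_mask <- function(h, w, cr, cc, r) {
  m <- matrix(FALSE, h, w)
  m[(row(m) - cr)^2 + (col(m) - cc)^2 <= r^2] <- TRUE
  m
}

test_that("nucleus detection counts, filters and orders components", {
  m <- disc_mask(100, 100, 20, 20, 10) | disc_mask(100, 100, 20, 70, 10) |
       disc_mask(100, 100, 75, 45, 10)
  nuc <- detect_nuclei(bmask(m), min_area_um2 = 5, max_area_um2 = 500)
  expect_length(nuc, 3)
  expect_equal(vapply(nuc, `[[`, 0, "id"), 1:3)
  # ids in raster (row-major) order of first pixel
  first_rows <- vapply(nuc, function(n) n$centroid[1], 0)
  expect_equal(order(first_rows), 1:3)

  # small disc excluded by the area window (r = 2 px -> ~3.2 um^2 at 0.5)
  m2 <- m | disc_mask(100, 100, 50, 90, 2)
  nuc2 <- detect_nuclei(bmask(m2), min_area_um2 = 5, max_area_um2 = 500)
  expect_length(nuc2, 3)
  expect_length(detect_nuclei(bmask(matrix(FALSE, 10, 10))), 0)
  expect_error(detect_nuclei(bmask(m), 10, 10))
})

test_that("components touching diagonally are single under 8-connectivity", {
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE
  m[11:16, 11:16] <- TRUE                   # touches corner-to-corner only
  lab8 <- flood_label(m, 8); lab4 <- flood_label(m, 4)
  expect_equal(max(lab8), 1)
  expect_equal(max(lab4), 2)
  nuc <- detect_nuclei(bmask(m), 0.5, 1e4)
  expect_length(nuc, 1)                     # one component under 8-conn
})

test_that("8-connected labelling matches a flood-fill oracle on random masks", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(40 * 40) < 0.3, 40, 40)
    nuc <- detect_nuclei(bmask(m), min_area_um2 = 0, max_area_um2 = 1e6)
    oracle <- flood_label(m, 8)
    expect_length(nuc, max(oracle))
    # identical pixel partition and identical raster ordering of ids
    for (n in nuc)
      expect_length(unique(oracle[n$idx]), 1)
    firsts <- vapply(nuc, function(n) min(oracle[n$idx]), 0)
    expect_equal(firsts, as.numeric(seq_along(nuc)))
  }
})

test_that("contiguity rule assigns whole components within 2 um", {
  # nucleus disc + a long branch whose nearest pixel is ~1.5 um away
  h <- 120; w <- 120; mpp <- 0.5
  nucm <- disc_mask(h, w, 60, 20, 6)
  iba <- matrix(FALSE, h, w)
  iba[60, 29:109] <- TRUE                    # 80-px (40-um) branch,
  iba[55:65, 50] <- TRUE                     # 3 px (1.5 um) from nucleus
  nuc <- detect_nuclei(bmask(nucm, mpp), 1, 1e4)
  seg <- assign_processes(bmask(iba, mpp), nuc, radius_um = 2)
  expect_equal(length(seg$cells[[1]]$process_idx), sum(iba))
  expect_length(seg$non_process_idx, 0)

  # isolated blob 3 um (6 px) from every nucleus -> non-process
  iba2 <- iba
  blob <- disc_mask(h, w, 20, 100, 4)
  iba2[blob] <- TRUE
  seg2 <- assign_processes(bmask(iba2, mpp), nuc, radius_um = 2)
  expect_equal(sort(seg2$non_process_idx), sort(which(blob)))
  expect_equal(length(seg2$cells[[1]]$process_idx), sum(iba))
})

test_that("the 2-um radius is inclusive and scale-aware", {
  h <- 40; w <- 40; mpp <- 0.5
  nucm <- matrix(FALSE, h, w); nucm[20, 10] <- TRUE
  nucm <- nucm | disc_mask(h, w, 20, 10, 3)
  nuc <- detect_nuclei(bmask(nucm, mpp), 0.5, 1e4)
  edge_col <- max(which(nucm[20, ]))
  iba <- matrix(FALSE, h, w)
  iba[20, edge_col + 4] <- TRUE              # exactly 4 px = 2.0 um away
  seg <- assign_processes(bmask(iba, mpp), nuc, radius_um = 2)
  expect_length(seg$non_process_idx, 0)      # inclusive at exactly 2 um
  iba2 <- matrix(FALSE, h, w)
  iba2[20, edge_col + 5] <- TRUE             # 2.5 um away
  seg2 <- assign_processes(bmask(iba2, mpp), nuc, radius_um = 2)
  expect_length(seg2$non_process_idx, 1)
})

test_that("shared components are partitioned like the BFS oracle", {
  h <- 60; w <- 160; mpp <- 0.5
  nucm <- disc_mask(h, w, 30, 20, 5) | disc_mask(h, w, 30, 140, 5)
  nuc <- detect_nuclei(bmask(nucm, mpp), 1, 1e4)
  expect_length(nuc, 2)
  # one bar touching both nuclei
  iba <- matrix(FALSE, h, w); iba[29:31, 15:145] <- TRUE
  seg <- assign_processes(bmask(iba, mpp), nuc, radius_um = 2)
  expect_length(seg$non_process_idx, 0)
  expect_gt(length(seg$cells[[1]]$process_idx), 0)
  expect_gt(length(seg$cells[[2]]$process_idx), 0)

  oracle <- bfs_partition_oracle(iba, lapply(nuc, `[[`, "idx"), 2, mpp)
  lab_pkg <- matrix(0L, h, w)
  for (k in 1:2) lab_pkg[seg$cells[[k]]$process_idx] <- k
  expect_identical(lab_pkg, oracle)
})

test_that("partition identity and radius monotonicity hold on random scenes", {
  for (seed in c(3, 14)) {
    p <- synth_params(n_cells = 10, seed = seed, noise_sd = 0,
                      background_od = 0, image_size_px = c(256L, 256L))
    out <- generate_microglia_image(p)
    seg <- segment_image(out$image)
    all_idx <- sort(c(seg$non_process_idx,
                      unlist(lapply(seg$cells, `[[`, "process_idx"))))
    expect_identical(all_idx, which(
      unmix_stains(rgb_to_od(out$image),
                   p$stain_vectors)$iba1_od >
        seg$params$iba1_threshold))          # exact tiling of the Iba1 mask
    expect_false(any(duplicated(all_idx)))

    # enlarging the radius never moves pixels into non-process
    od <- rgb_to_od(out$image)
    sm <- unmix_stains(od, p$stain_vectors, p$microns_per_pixel)
    im <- threshold_channel(sm$iba1_od, "otsu",
                            microns_per_pixel = p$microns_per_pixel)
    pm <- threshold_channel(sm$pu1_od, "otsu",
                            microns_per_pixel = p$microns_per_pixel)
    nuc <- detect_nuclei(pm)
    s2 <- assign_processes(im, nuc, radius_um = 2)
    s4 <- assign_processes(im, nuc, radius_um = 4)
    expect_true(all(s4$non_process_idx %in% s2$non_process_idx))
  }
})

test_that("mask scale or shape mismatches are rejected", {
  nucm <- disc_mask(30, 30, 15, 15, 4)
  nuc <- detect_nuclei(bmask(nucm, 0.5), 1, 1e4)
  expect_error(assign_processes(bmask(nucm, 1.0), nuc), "scale mismatch")
  expect_error(assign_processes(bmask(matrix(FALSE, 20, 20), 0.5), nuc),
               "shape mismatch")
})
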