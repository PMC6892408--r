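#' Pixel-level accuracy of a segmentation against synthetic ground truth
#'
#' Matches every segmented cell to the ground-truth cell with the nearest
#' nucleus centre, then scores the assigned Iba1 masks pixel-wise:
#' recall = matched pixels / all ground-truth cell pixels,
#' precision = matched pixels / all assigned pixels. Unmatched ground-truth
#' cells therefore count fully against recall and spurious segmented cells
#' against precision.
#'
#' @param seg A `segmentation_result` from the same image.
#' @param ground_truth The generator's `ground_truth`.
#' @return List with `recall`, `precision`, `tp`, `fp`, `fn` (pixel counts).
#' @export
segmentation_accuracy <- function(seg, ground_truth) {
  stopifnot(inherits(seg, "segmentation_result"),
            inherits(ground_truth, "ground_truth"))
  gt_cells <- ground_truth$cells
  total_gt <- sum(vapply(gt_cells, function(g) length(g$iba1_idx), 0L))
  total_seg <- sum(vapply(seg$cells, function(x) length(x$process_idx), 0L))
  tp <- 0L
  if (length(gt_cells))
    for (cell in seg$cells) {
      if (!length(cell$process_idx)) next
      ctr <- cell$nucleus$centroid
      d2 <- vapply(gt_cells, function(g)
        sum((g$center_px - ctr)^2), numeric(1))
      g <- gt_cells[[which.min(d2)]]
      tp <- tp + length(intersect(cell$process_idx, g$iba1_idx))
    }
  list(recall = if (total_gt > 0) tp / total_gt else NA_real_,
       precision = if (total_seg > 0) tp / total_seg else NA_real_,
       tp = tp, fp = total_seg - tp, fn = total_gt - tp)
}
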