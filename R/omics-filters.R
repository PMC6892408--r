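# The explicit numeric genomics rules used alongside the imaging assay:
# Benjamini-Hochberg FDR, the joint TPM / fold-change / FDR DEG criteria,
# top-k DEG list construction and overlaps, top-variable-gene selection,
# TSS-window ChIP peak filtering, and double-normalised qPCR expression.

#' Default differential-expression filter criteria
#'
#' A gene is called differential when mean expression exceeds 4 TPM, the
#' FDR is below 0.05, and the fold change differs from unity by at least
#' 30% (on the ratio scale: `FC >= 1.3` or `FC <= 1/1.3`).
#'
#' @param tpm_min Minimum mean TPM (strict, `> tpm_min`).
#' @param fc_min_ratio Minimal fold-change ratio (> 1).
#' @param fdr_max FDR ceiling (strict, `< fdr_max`), in (0, 1).
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(tpm_min = 4, fc_min_ratio = 1.3, fdr_max = 0.05) {
  stopifnot(tpm_min >= 0, fc_min_ratio > 1, fdr_max > 0, fdr_max < 1)
  structure(list(tpm_min = tpm_min, fc_min_ratio = fc_min_ratio,
                 fdr_max = fdr_max), class = "filter_criteria")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adj_(i) = min_{j >= rank(i)} ( p_(j) * m / j )`, capped at 1;
#' order-preserving in p. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (values outside
#'   are an error).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the joint TPM / fold-change / FDR differential-expression filter
#'
#' A gene passes when `mean_tpm > tpm_min` AND `fdr < fdr_max` AND the
#' fold change clears the ratio criterion. Down-regulation is read
#' symmetrically on the ratio scale by default (`FC <= 1/fc_min_ratio`);
#' `down_rule = "complement"` uses the alternative
#' `FC <= 2 - fc_min_ratio` reading (e.g. 0.7 for a 30% difference).
#' If the `fdr` column is missing or all-NA it is computed from `p` with
#' [bh_adjust()] first.
#'
#' @param table data.frame with `gene_id`, `mean_tpm`, `fold_change`, `p`,
#'   and optionally `fdr`.
#' @param criteria A [filter_criteria()].
#' @param down_rule `"reciprocal"` (default) or `"complement"`.
#' @return List with `up` and `down` character vectors of gene ids and the
#'   annotated `table` (with `fdr`, `deg`, `direction` columns).
#' @export
deg_filter <- function(table, criteria = filter_criteria(),
                       down_rule = c("reciprocal", "complement")) {
  down_rule <- match.arg(down_rule)
  stopifnot(inherits(criteria, "filter_criteria"),
            all(c("gene_id", "mean_tpm", "fold_change", "p") %in%
                  names(table)))
  if (is.null(table$fdr) || all(is.na(table$fdr)))
    table$fdr <- bh_adjust(table$p)
  down_cut <- if (down_rule == "reciprocal") 1 / criteria$fc_min_ratio
              else 2 - criteria$fc_min_ratio
  up_fc <- table$fold_change >= criteria$fc_min_ratio
  down_fc <- table$fold_change <= down_cut
  pass <- table$mean_tpm > criteria$tpm_min &
    table$fdr < criteria$fdr_max & (up_fc | down_fc)
  table$deg <- pass
  table$direction <- ifelse(pass & up_fc, "up",
                            ifelse(pass & down_fc, "down", "none"))
  list(up = table$gene_id[pass & up_fc],
       down = table$gene_id[pass & down_fc],
       table = table)
}

#' Top-k DEG lists per comparison and their ordered union
#'
#' Within each comparison the genes are sorted by ascending p (ties broken
#' by gene id) and the first `k` taken; the union preserves first-seen
#' order across comparisons. Fewer than `k` genes triggers a warning and
#' takes all.
#'
#' @param tables Named list of data.frames (columns `gene_id`, `p`),
#'   typically the DEG-filtered table of each comparison.
#' @param k Per-comparison list size (>= 1).
#' @return List with `per_comparison` (list of character vectors) and
#'   `union` (character vector).
#' @export
top_deg_lists <- function(tables, k) {
  stopifnot(k >= 1, is.list(tables), length(tables) >= 1)
  per <- lapply(tables, function(tb) {
    stopifnot(all(c("gene_id", "p") %in% names(tb)))
    if (nrow(tb) < k)
      warning(sprintf("only %d DEGs available, fewer than k = %d",
                      nrow(tb), k))
    ord <- order(tb$p, tb$gene_id)
    utils::head(tb$gene_id[ord], k)
  })
  list(per_comparison = per, union = unique(unlist(per, use.names = FALSE)))
}

#' Exact two-set overlap partition counts
#'
#' @param a,b Character vectors (duplicates ignored).
#' @return Named integer vector `c(a_only, both, b_only)`.
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- length(intersect(a, b))
  c(a_only = length(a) - both, both = both, b_only = length(b) - both)
}

#' Select the k most variable genes of an expression matrix
#'
#' Genes (rows) ranked by variance across samples, descending, ties broken
#' by gene id; intended for an already variance-stabilised matrix.
#'
#' @param matrix Numeric genes x samples matrix with row names.
#' @param k Number of genes (default 500).
#' @return Character vector of gene ids, length `k`.
#' @export
top_variable_genes <- function(matrix, k = 500) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  v <- apply(matrix, 1, stats::var)
  ok <- is.finite(v)
  if (k > sum(ok)) stop("k exceeds the number of genes with finite variance")
  ord <- order(-v[ok], rownames(matrix)[ok])
  rownames(matrix)[ok][ord][seq_len(k)]
}

#' Filter ChIP peaks by TSS window, read support and effect criteria
#'
#' A peak is retained when it lies within `window_bp` of the transcription
#' start site (inclusive; signed distance, negative = upstream) and has at
#' least `min_reads` reads in at least one genotype. A retained peak is
#' significant when additionally the fold change is at least `fc_min` in
#' either direction (`FC >= fc_min` or `FC <= 1/fc_min`) and
#' `idr < idr_max`.
#'
#' @param peaks data.frame with `peak_id`, `tss_distance`, `fold_change`,
#'   `idr`, and one or more `reads_*` columns (read counts per genotype).
#' @param window_bp TSS window half-width in bp (default 1000).
#' @param min_reads Minimum reads in the best-supported genotype (default 4).
#' @param fc_min Minimal fold-change ratio (default 2).
#' @param idr_max IDR ceiling (default 0.05, strict).
#' @return List with `retained` and `significant` data.frames
#'   (`significant` is a subset of `retained`).
#' @export
chip_peak_filter <- function(peaks, window_bp = 1000, min_reads = 4,
                             fc_min = 2.0, idr_max = 0.05) {
  stopifnot(all(c("peak_id", "tss_distance", "fold_change", "idr") %in%
                  names(peaks)))
  read_cols <- grep("^reads_", names(peaks), value = TRUE)
  if (length(read_cols) == 0) stop("no reads_* columns found")
  max_reads <- do.call(pmax, peaks[read_cols])
  retained <- abs(peaks$tss_distance) <= window_bp & max_reads >= min_reads
  signif <- retained &
    (peaks$fold_change >= fc_min | peaks$fold_change <= 1 / fc_min) &
    peaks$idr < idr_max
  list(retained = peaks[retained, , drop = FALSE],
       significant = peaks[signif, , drop = FALSE])
}

#' Doubly normalised qPCR relative expression (delta-delta-Ct)
#'
#' Per sample, expression relative to the reference gene is
#' `2^-(Ct_gene - Ct_reference)`; the result is then divided by the mean
#' relative expression of the reference group (so that group averages to 1).
#' Samples with a missing Ct in either assay are dropped with a warning.
#'
#' @param ct_gene,ct_reference Matched per-sample Ct vectors.
#' @param group_labels Group label per sample.
#' @param reference_group Label of the normalising group (default `"WT"`,
#'   must be non-empty after dropping).
#' @return Named numeric vector of relative expression for the retained
#'   samples (names from `ct_gene` if present, else sample positions).
#' @export
qpcr_relative_expression <- function(ct_gene, ct_reference, group_labels,
                                     reference_group = "WT") {
  stopifnot(length(ct_gene) == length(ct_reference),
            length(ct_gene) == length(group_labels))
  nm <- names(ct_gene)
  if (is.null(nm)) nm <- as.character(seq_along(ct_gene))
  ok <- !is.na(ct_gene) & !is.na(ct_reference)
  if (any(!ok))
    warning(sprintf("%d sample(s) dropped for missing Ct", sum(!ok)))
  ct_gene <- ct_gene[ok]; ct_reference <- ct_reference[ok]
  group_labels <- group_labels[ok]; nm <- nm[ok]
  ref <- group_labels == reference_group
  if (!any(ref)) stop("reference group is empty")
  rel <- 2^-(ct_gene - ct_reference)
  out <- rel / mean(rel[ref])
  names(out) <- nm
  out
}
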