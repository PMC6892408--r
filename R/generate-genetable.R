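#' Generate a synthetic per-gene statistics table with known DE labels
#'
#' Emulates the per-gene summary a differential-expression engine exports
#' (mean TPM, fold change, raw p), with a known set of truly differential
#' genes. Null genes carry uniform p-values and fold changes near 1; true
#' DE genes carry log-uniform fold changes in the configured range (half
#' up, half down on the ratio scale) and small p-values. The FDR column is
#' left missing and is computed downstream by [bh_adjust()].
#'
#' @param n_genes Number of genes.
#' @param n_true_de Number of truly differential genes (`<= n_genes`).
#' @param effect Length-2 `c(min, max)` fold-change range (ratio scale,
#'   both > 1) for true DE genes; the realised FC is the value or its
#'   reciprocal.
#' @param null_fc_sd s.d. of log2 fold change for null genes.
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters of mean TPM.
#' @param seed Integer seed; the table is a pure function of the arguments.
#' @return data.frame with columns `gene_id`, `mean_tpm`, `fold_change`,
#'   `p`, `fdr` (all `NA`) and the ground-truth label `true_de`.
#' @export
generate_gene_stat_table <- function(n_genes = 10000, n_true_de = 500,
                                     effect = c(1.5, 8), null_fc_sd = 0.05,
                                     tpm_meanlog = log(20), tpm_sdlog = 1.2,
                                     seed = 1L) {
  stopifnot(n_true_de <= n_genes, n_true_de >= 0,
            length(effect) == 2, all(effect > 1), effect[2] >= effect[1])
  set.seed(seed)
  true_de <- logical(n_genes)
  true_de[sample.int(n_genes, n_true_de)] <- TRUE

  fc <- 2^stats::rnorm(n_genes, 0, null_fc_sd)
  p <- stats::runif(n_genes)
  if (n_true_de > 0) {
    mag <- exp(stats::runif(n_true_de, log(effect[1]), log(effect[2])))
    dirn <- sample(c(TRUE, FALSE), n_true_de, replace = TRUE)
    fc[true_de] <- ifelse(dirn, mag, 1 / mag)
    p[true_de] <- 10^-stats::runif(n_true_de, 3, 12)
  }
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    mean_tpm = stats::rlnorm(n_genes, tpm_meanlog, tpm_sdlog),
    fold_change = fc,
    p = p,
    fdr = NA_real_,
    true_de = true_de,
    stringsAsFactors = FALSE)
}
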