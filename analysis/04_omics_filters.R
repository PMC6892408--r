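#!/usr/bin/env Rscript
# Step 4 -- the genomics threshold rules on synthetic tables.
#
# Generates per-gene statistics tables for two comparisons (young and aged
# KO vs WT), applies BH adjustment and the joint TPM/FC/FDR DEG criteria,
# builds top-100 lists and their union, overlaps the DEG sets, filters a
# synthetic ChIP-peak table by the TSS-window/read/FC/IDR rules, and
# demonstrates the doubly normalised qPCR quantification.

suppressMessages({
  library(optparse)
  library(mgmorph)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 7L))))
dir.create("results", showWarnings = FALSE)

tables <- list(
  young = generate_gene_stat_table(n_genes = 12000, n_true_de = 400,
                                   seed = opts$seed),
  aged = generate_gene_stat_table(n_genes = 12000, n_true_de = 120,
                                  seed = opts$seed + 1L))
deg <- lapply(tables, deg_filter)
for (cmp in names(deg)) {
  res <- deg[[cmp]]
  cat(sprintf("%s KO vs WT: %d up, %d down (of %d genes)\n",
              cmp, length(res$up), length(res$down), nrow(tables[[cmp]])))
  write.csv(res$table[res$table$deg, ],
            sprintf("results/deg_%s.csv", cmp), row.names = FALSE)
}

top <- top_deg_lists(lapply(deg, function(r) r$table[r$table$deg, ]), k = 100)
cat(sprintf("Top-100 union across the two time points: %d genes\n",
            length(top$union)))
writeLines(top$union, "results/top100_union.txt")

ov <- set_overlap(c(deg$young$up, deg$young$down),
                  c(deg$aged$up, deg$aged$down))
cat(sprintf("DEG set overlap: %d young-only, %d shared, %d aged-only\n",
            ov["a_only"], ov["both"], ov["b_only"]))

set.seed(opts$seed)
peaks <- data.frame(
  peak_id = sprintf("peak%04d", 1:2000),
  tss_distance = round(rnorm(2000, 0, 900)),
  reads_wt = rpois(2000, 6), reads_ko = rpois(2000, 6),
  fold_change = 2^rnorm(2000, 0, 0.8),
  idr = runif(2000))
pf <- chip_peak_filter(peaks)
cat(sprintf("ChIP peaks: %d retained (TSS window + reads), %d significant\n",
            nrow(pf$retained), nrow(pf$significant)))
write.csv(pf$significant, "results/chip_significant.csv", row.names = FALSE)

ct_gene <- c(24.1, 24.4, 23.9, 23.2, 23.0, 23.4)
ct_gapdh <- c(18.0, 18.2, 17.9, 18.1, 17.8, 18.0)
grp <- rep(c("WT", "KO"), each = 3)
rel <- qpcr_relative_expression(ct_gene, ct_gapdh, grp)
cat("qPCR relative expression (WT-normalised):\n")
print(round(tapply(rel, grp, mean), 3))
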