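test_that("BH adjustment matches the literal step-up formula", {
  expect_equal(bh_adjust(rep(0.02, 7)), rep(0.02, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(50)^2
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))    # order-preserving
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("DEG criteria apply the joint TPM/FC/FDR rule", {
  tb <- data.frame(
    gene_id = c("up_ok", "low_tpm", "down_ok", "weak_fc", "high_fdr",
                "down_borderline"),
    mean_tpm = c(5, 3.9, 10, 50, 20, 8),
    fold_change = c(1.4, 2.0, 0.70, 1.2, 3.0, 0.75),
    p = c(1e-4, 1e-5, 1e-4, 1e-6, 0.9, 1e-4),
    fdr = c(0.04, 0.001, 0.01, 0.001, 0.9, 0.01))
  res <- deg_filter(tb)
  expect_true("up_ok" %in% res$up)
  expect_false("low_tpm" %in% c(res$up, res$down))   # needs > 4 TPM
  expect_true("down_ok" %in% res$down)               # 0.70 <= 1/1.3
  expect_true("down_borderline" %in% res$down)       # 0.75 <= 0.769
  expect_false("weak_fc" %in% c(res$up, res$down))
  expect_false("high_fdr" %in% c(res$up, res$down))

  # alternative complement reading of "30% difference": down iff FC <= 0.7
  res2 <- deg_filter(tb, down_rule = "complement")
  expect_true("down_ok" %in% res2$down)
  expect_false("down_borderline" %in% res2$down)

  # fdr computed from p when missing
  tb$fdr <- NULL
  res3 <- deg_filter(tb)
  expect_equal(res3$table$fdr, bh_adjust(tb$p))

  # idempotence: filtering the passing subset returns the same set
  sub <- res$table[res$table$deg, ]
  res4 <- deg_filter(sub)
  expect_setequal(c(res4$up, res4$down), c(res$up, res$down))
})

test_that("DEG filter matches a brute-force reimplementation on random tables", {
  for (seed in 1:5) {
    tab <- generate_gene_stat_table(n_genes = 400, n_true_de = 40,
                                    seed = seed)
    res <- deg_filter(tab)
    fdr <- bh_brute(tab$p)
    pass <- tab$mean_tpm > 4 & fdr < 0.05 &
      (tab$fold_change >= 1.3 | tab$fold_change <= 1 / 1.3)
    expect_setequal(c(res$up, res$down), tab$gene_id[pass])
    expect_setequal(res$up, tab$gene_id[pass & tab$fold_change >= 1.3])
  }
})

test_that("BH keeps the realized false-discovery proportion controlled", {
  fdp <- vapply(1:200, function(s) {
    tab <- generate_gene_stat_table(n_genes = 1000, n_true_de = 100,
                                    seed = 4000 + s)
    res <- deg_filter(tab)
    called <- c(res$up, res$down)
    if (!length(called)) return(0)
    mean(!tab$true_de[match(called, tab$gene_id)])
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 2.576 * stats::sd(fdp) / sqrt(200))
})

test_that("top-k DEG lists and unions preserve order and bounds", {
  mk <- function(ids, p) data.frame(gene_id = ids, p = p)
  t1 <- mk(sprintf("a%03d", 1:150), seq(0.001, 0.15, length.out = 150))
  t2 <- mk(sprintf("b%03d", 1:150), seq(0.001, 0.15, length.out = 150))
  t3 <- mk(sprintf("c%03d", 1:150), seq(0.001, 0.15, length.out = 150))
  disjoint <- top_deg_lists(list(t1, t2, t3), k = 100)
  expect_length(disjoint$union, 300)
  identical3 <- top_deg_lists(list(t1, t1, t1), k = 100)
  expect_length(identical3$union, 100)
  expect_gte(length(disjoint$union), 100)
  expect_lte(length(disjoint$union), 300)

  # ties broken by gene id; short tables warn and return everything
  tied <- mk(c("z", "y", "x"), c(0.01, 0.01, 0.01))
  expect_equal(top_deg_lists(list(tied), k = 2)$per_comparison[[1]],
               c("x", "y"))
  expect_warning(res <- top_deg_lists(list(tied), k = 5), "fewer")
  expect_length(res$union, 3)
})

test_that("set overlaps partition exactly", {
  expect_equal(set_overlap(c("x", "y", "z"), c("y", "z", "w")),
               c(a_only = 1L, both = 2L, b_only = 1L))
  expect_equal(set_overlap(c("a", "b"), c("c")),
               c(a_only = 2L, both = 0L, b_only = 1L))
  expect_equal(set_overlap(c("a"), c("a", "b", "c")),
               c(a_only = 0L, both = 1L, b_only = 2L))
})

test_that("top variable genes rank by variance with stable ties", {
  m <- rbind(g_high = c(0, 4, 8), g_mid = c(0, 2, 4), g_low = c(0, 1, 2),
             g_const = c(3, 3, 3))
  expect_equal(top_variable_genes(m, 2), c("g_high", "g_mid"))
  expect_equal(top_variable_genes(m, 3), c("g_high", "g_mid", "g_low"))
  expect_equal(top_variable_genes(m[, c(3, 1, 2)], 3),
               top_variable_genes(m, 3))      # column-order invariant
  expect_error(top_variable_genes(m, 5), "finite variance")
})

test_that("ChIP peak filtering applies window, reads, FC and IDR rules", {
  pk <- data.frame(
    peak_id = c("good", "far", "weak", "edge_window", "edge_reads",
                "down_fc", "idr_edge"),
    tss_distance = c(-800, 1500, 0, -1000, 200, 300, 400),
    reads_wt = c(5, 10, 3, 6, 4, 9, 8),
    reads_ko = c(1, 10, 3, 2, 1, 2, 9),
    fold_change = c(5, 3, 4, 2.5, 2, 0.5, 3),
    idr = c(0.01, 0.01, 0.01, 0.04, 0.04, 0.01, 0.05))
  res <- chip_peak_filter(pk)
  expect_setequal(res$retained$peak_id,
                  c("good", "edge_window", "edge_reads", "down_fc",
                    "idr_edge"))
  expect_false("far" %in% res$retained$peak_id)     # outside 1000 bp
  expect_false("weak" %in% res$retained$peak_id)    # < 4 reads everywhere
  expect_setequal(res$significant$peak_id,
                  c("good", "edge_window", "edge_reads", "down_fc"))
  expect_false("idr_edge" %in% res$significant$peak_id)  # idr < 0.05 strict
  expect_true(all(res$significant$peak_id %in% res$retained$peak_id))
  # idempotence on the retained set
  res2 <- chip_peak_filter(res$retained)
  expect_setequal(res2$retained$peak_id, res$retained$peak_id)
})

test_that("qPCR double normalisation matches hand-computed values", {
  g <- c(20, 21, 20, 22); ref <- c(20, 21, 20, 20)
  grp <- c("WT", "WT", "KO", "KO")
  out <- qpcr_relative_expression(g, ref, grp)
  expect_equal(unname(out), c(1, 1, 1, 0.25))  # WT mean exactly 1
  expect_equal(mean(out[grp == "WT"]), 1)

  # one cycle above a WT baseline of delta-Ct 0 halves expression
  out2 <- qpcr_relative_expression(c(10, 11), c(10, 10), c("WT", "KO"))
  expect_equal(unname(out2), c(1, 0.5))
  # doubling: delta-Ct one cycle below the reference group
  out3 <- qpcr_relative_expression(c(10, 9), c(10, 10), c("WT", "KO"))
  expect_equal(unname(out3), c(1, 2))

  expect_warning(
    out4 <- qpcr_relative_expression(c(10, NA, 12), c(10, 10, 10),
                                     c("WT", "WT", "KO")),
    "dropped")
  expect_length(out4, 2)
  expect_error(
    suppressWarnings(qpcr_relative_expression(c(NA_real_, 1), c(10, 10),
                                              c("WT", "KO"))),
    "reference group is empty")
})
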