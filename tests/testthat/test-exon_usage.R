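test_that("gene models flatten into disjoint boundary-projected bins", {
  ts <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g1", exons = list(c(100, 200))),
    b = list(chrom = "c", strand = "+", gene = "g1", exons = list(c(100, 300)))))
  bins <- flatten_gene_models(ts)
  expect_equal(bins$start, c(100L, 200L))
  expect_equal(bins$end, c(200L, 300L))
  expect_equal(bins$source_transcripts, c("a,b", "b"))

  # single-isoform gene: bins = its exons
  ts1 <- make_ts(list(a = list(chrom = "c", strand = "+", gene = "g",
                               exons = list(c(0, 100), c(200, 350)))))
  b1 <- flatten_gene_models(ts1)
  expect_equal(b1[, c("start", "end")], data.frame(start = c(0L, 200L),
                                                   end = c(100L, 350L)),
               ignore_attr = TRUE)

  # bins overlapping a second gene's exons are flagged ambiguous
  ts2 <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g1", exons = list(c(0, 100))),
    b = list(chrom = "c", strand = "-", gene = "g2", exons = list(c(50, 150)))))
  b2 <- flatten_gene_models(ts2)
  expect_true(all(b2$ambiguous))
})

test_that("flattening invariants hold and match the per-nucleotide oracle", {
  g <- simulate_genome(1, 6e5, 0.4, seed = 71)
  sim <- simulate_annotation(g, n_genes = 25, seed = 71)
  bins <- flatten_gene_models(sim$models)
  ex <- sim$models$exons
  tt <- tx_table(sim$models)
  ex$gene_id <- tt$gene_id[match(ex$transcript_id, tt$transcript_id)]
  for (gid in unique(bins$gene_id)[1:10]) {
    b <- bins[bins$gene_id == gid, ]
    e <- ex[ex$gene_id == gid, ]
    # disjoint
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    # union of bins == union of exons
    ir_b <- IRanges::reduce(IRanges::IRanges(b$start + 1, b$end))
    ir_e <- IRanges::reduce(IRanges::IRanges(e$start + 1, e$end))
    expect_equal(as.data.frame(ir_b), as.data.frame(ir_e))
    # boundaries subset of exon boundaries
    expect_true(all(c(b$start, b$end) %in% c(e$start, e$end)))
    # equals the naive per-nucleotide oracle
    orc <- oracle_flatten(e)
    expect_equal(b[, c("start", "end", "source_transcripts")], orc,
                 ignore_attr = TRUE)
  }
})

test_that("read counting honors overlap, splicing and unknown chromosomes", {
  bins <- data.frame(gene_id = "g", bin_id = c("g:001", "g:002"),
                     chrom = "c", strand = "+",
                     start = c(100L, 200L), end = c(200L, 300L),
                     source_transcripts = "a", ambiguous = FALSE)
  reads <- list(
    s1 = data.frame(read_id = c("r1", "r1", "r2", "r3"),
                    chrom = c("c", "c", "c", "zzz"),
                    start = c(150L, 250L, 120L, 0L),
                    end = c(190L, 290L, 180L, 50L)),
    s2 = data.frame(read_id = character(), chrom = character(),
                    start = integer(), end = integer()))
  res <- count_reads_in_bins(reads, bins)
  # r1 spliced over both bins: +1 each; r2 only bin 1; r3 unassigned
  expect_equal(unname(res$counts[, "s1"]), c(2L, 1L))
  expect_equal(unname(res$counts[, "s2"]), c(0L, 0L))
  expect_equal(unname(res$n_unassigned["s1"]), 1L)

  # a read overlapping by a single nt counts at min_overlap 1 but not 10
  r1 <- list(s = data.frame(read_id = "r", chrom = "c", start = 199L, end = 205L))
  expect_equal(unname(count_reads_in_bins(r1, bins, min_overlap = 1)$counts[, 1]), c(1L, 1L))
  expect_equal(unname(count_reads_in_bins(r1, bins, min_overlap = 10)$counts[, 1]), c(0L, 0L))
})

test_that("differential usage tests the bin-vs-rest contrast", {
  bins <- data.frame(gene_id = rep(c("g1", "g2"), c(3, 1)),
                     bin_id = c("g1:1", "g1:2", "g1:3", "g2:1"),
                     chrom = "c", strand = "+",
                     start = c(0L, 100L, 200L, 500L), end = c(100L, 200L, 300L, 600L),
                     source_transcripts = "x", ambiguous = FALSE)
  counts <- rbind(
    "g1:1" = c(100L, 110L, 100L, 105L),
    "g1:2" = c(100L, 95L, 800L, 820L),   # ~8x usage shift in B
    "g1:3" = c(100L, 100L, 100L, 95L),
    "g2:1" = c(50L, 60L, 55L, 50L))
  cond <- c("A", "A", "B", "B")
  res <- differential_usage(counts, bins, cond)
  r2 <- res[res$bin_id == "g1:2", ]
  expect_lt(r2$adj_p_value, 0.05)
  expect_gt(r2$log2_fc, 2)
  # single-bin gene untestable
  expect_false(res$tested[res$bin_id == "g2:1"])
  expect_true(is.na(res$p_value[res$bin_id == "g2:1"]))
  # equal usage ratios across conditions: fold-change 0, p = 1
  counts_eq <- counts; counts_eq["g1:2", ] <- c(100L, 100L, 100L, 100L)
  counts_eq[] <- rep(counts_eq[, 1], 4)
  res_eq <- differential_usage(counts_eq, bins, cond)
  expect_true(all(abs(res_eq$log2_fc[res_eq$tested]) < 1e-12))
  expect_true(all(res_eq$p_value[res_eq$tested] > 0.99))
  # low-count gate
  counts2 <- counts; counts2["g1:3", ] <- c(1L, 1L, 1L, 1L)
  res2 <- differential_usage(counts2, bins, cond)
  expect_false(res2$tested[res2$bin_id == "g1:3"])
  # adjusted p respects ordering
  expect_true(all(res$adj_p_value >= res$p_value - 1e-12, na.rm = TRUE))
})

test_that("null simulations are calibrated and planted shifts are detected", {
  g <- simulate_genome(1, 2e6, 0.4, seed = 73)
  sim <- simulate_annotation(g, n_genes = 100, seed = 73)
  bins <- flatten_gene_models(sim$models)
  # null: overdispersed counts, no effect
  bc0 <- simulate_bin_counts(bins, samples_per_condition = 3,
                             baseline_depth = 500, planted_effects = NULL,
                             dispersion = 0.05, seed = 74)
  du0 <- differential_usage(bc0$counts, bins, bc0$condition)
  expect_lte(mean(du0$adj_p_value[du0$tested] < 0.05), 0.05)
  # power: one bin per gene shifted by log2 FC 3
  set.seed(75)
  pick <- vapply(split(seq_len(nrow(bins)), bins$gene_id),
                 function(i) if (length(i) == 1) i else sample(i, 1), integer(1))
  eff <- data.frame(bin_id = bins$bin_id[pick], log2_shift = 3)
  bc1 <- simulate_bin_counts(bins, samples_per_condition = 3,
                             baseline_depth = 500, planted_effects = eff,
                             dispersion = 0.05, seed = 76)
  du1 <- differential_usage(bc1$counts, bins, bc1$condition)
  planted <- du1[match(eff$bin_id, du1$bin_id), ]
  expect_gte(mean(planted$adj_p_value < 0.05 & planted$tested, na.rm = TRUE), 0.8)
  expect_gt(mean(planted$log2_fc, na.rm = TRUE), 2)
})
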