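test_that("genome simulation is seeded, GC-controlled and bounded", {
  g1 <- simulate_genome(2, c(5000, 3000), 0.5, seed = 42)
  g2 <- simulate_genome(2, c(5000, 3000), 0.5, seed = 42)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(names(g1), c("chr1", "chr2"))
  expect_equal(unname(Biostrings::width(g1)), c(5000L, 3000L))

  gc_only <- simulate_genome(1, 2000, 0.999, seed = 1)
  f <- Biostrings::alphabetFrequency(gc_only)[1, c("A", "C", "G", "T")]
  expect_equal(unname(f[["A"]] + f[["T"]]), 0, tolerance = 10)

  g3 <- simulate_genome(1, 1e5, 0.4, seed = 3)
  gc <- sum(Biostrings::alphabetFrequency(g3)[1, c("C", "G")]) / 1e5
  expect_lt(abs(gc - 0.4), 3 * sqrt(0.4 * 0.6 / 1e5))
})

test_that("annotation simulation plants what its truth tables record", {
  g <- simulate_genome(1, 1e6, 0.4, seed = 81)
  sim <- simulate_annotation(g, n_genes = 50, seed = 81)
  # byte-identical regeneration under the same seed
  sim2 <- simulate_annotation(simulate_genome(1, 1e6, 0.4, seed = 81),
                              n_genes = 50, seed = 81)
  expect_identical(sim$models$exons, sim2$models$exons)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))

  # every planted event is found by enumeration at its exact coordinates
  ev <- enumerate_events(sim$models)
  tr <- sim$truth$events
  expect_true(all(paste(tr$kind, tr$gene_id, tr$var_start, tr$var_end) %in%
                    paste(ev$kind, ev$gene_id, ev$var_start, ev$var_end)))
  # all junctions canonical by construction
  ann <- annotation_index(sim$models)
  jx <- classify_junctions(sim$models, sim$genome, ann)
  expect_equal(mean(jx$canonical), 1)
  # requested non-canonical fraction shows up
  simnc <- simulate_annotation(simulate_genome(1, 1e6, 0.4, seed = 82),
                               n_genes = 50, noncanonical_fraction = 0.3, seed = 82)
  jnc <- classify_junctions(simnc$models, simnc$genome, annotation_index(simnc$models))
  expect_gt(mean(!jnc$canonical), 0.1)
})

test_that("event mix proportions in the truth table follow the multinomial draw", {
  g <- simulate_genome(1, 4e6, 0.4, seed = 83)
  mix <- c(IR = 0.34, ES = 0.12, ME = 0.135, MX = 0.135, A3SS = 0.135, A5SS = 0.135)
  sim <- simulate_annotation(g, n_genes = 180, isoforms_per_gene = 4,
                             event_mix = mix, seed = 83)
  tr <- sim$truth$events
  expect_gte(nrow(tr), 400)
  obs <- table(factor(tr$kind, names(mix))) / nrow(tr)
  for (k in names(mix))
    expect_lt(abs(obs[[k]] - mix[[k]]), 3 * sqrt(mix[[k]] * (1 - mix[[k]]) / nrow(tr)),
              label = paste("kind", k))
})

test_that("long-read simulation obeys its artifact and truncation switches", {
  g <- simulate_genome(1, 1e6, 0.4, seed = 84)
  sim <- simulate_annotation(g, n_genes = 50, seed = 84)
  ann <- annotation_index(sim$models)

  # clean channel: everything FSM with zero terminal distances
  rd0 <- simulate_long_reads(sim, 100, p_truncate = 0, p_intraprime = 0,
                             p_rts = 0, seed = 85)
  calls <- classify_transcripts(rd0$reads, ann)
  expect_true(all(calls$category == "FSM"))
  expect_true(all(calls$dist5 == 0 & calls$dist3 == 0))
  expect_true(all(rd0$truth$truncation == 0))

  # forced intrapriming: downstream A-fraction >= 0.8 for every read
  rd1 <- simulate_long_reads(sim, 100, p_truncate = 0, p_intraprime = 1,
                             p_rts = 0, seed = 86, ensure_full_length = FALSE)
  af <- intrapriming_fraction(rd1$reads, sim$genome)
  expect_true(all(af[rd1$truth$read_id[rd1$truth$intraprime]] >= 0.8))
  expect_true(all(rd1$truth$intraprime))

  # truncation cuts the 5' end only: the 3' terminus never moves
  rd2 <- simulate_long_reads(sim, 200, p_truncate = 1, seed = 87,
                             ensure_full_length = FALSE)
  tt2 <- tx_table(rd2$reads)
  src <- tx_table(sim$models)
  m <- match(rd2$truth$source_isoform, src$transcript_id)
  plus <- tt2$strand == "+"
  expect_true(all(tt2$end[plus] == src$end[m][plus]))
  expect_true(all(tt2$start[!plus] == src$start[m][!plus]))
  expect_true(all(tt2$n_exons > 1))   # at least one intron retained
  # identical seed regenerates identical reads
  rd2b <- simulate_long_reads(sim, 200, p_truncate = 1, seed = 87,
                              ensure_full_length = FALSE)
  expect_identical(rd2$reads$exons, rd2b$reads$exons)
})

test_that("junction table simulation controls support and dropout", {
  g <- simulate_genome(1, 6e5, 0.4, seed = 88)
  sim <- simulate_annotation(g, n_genes = 30, seed = 88)
  jx <- introns_table(sim$models)
  jt <- simulate_junction_table(jx, depth = 20, dropout = 0, seed = 89)
  expect_true(all(jt$unique_read_support > 0))
  expect_lt(abs(mean(jt$unique_read_support) - 20), 3 * sqrt(20 / nrow(jt)))
  # dropout 0: the support filter removes nothing
  fr <- filter_isoforms(sim$models, sim$genome, annotation_index(sim$models), jt,
                        a_threshold = 1.01)   # disable the intrapriming rule
  expect_true(all(fr$report$n_unsupported == 0))
  # full dropout: everything unsupported
  jt1 <- simulate_junction_table(jx, depth = 20, dropout = 1, seed = 90)
  expect_true(all(jt1$unique_read_support == 0))
  # the SJ dialect round-trips
  f <- tempfile()
  write_junction_table(jt, f)
  expect_equal(read_junction_table(f), jt[, c("chrom", "start", "end", "strand",
                                              "unique_read_support")],
               ignore_attr = TRUE)
})

test_that("bin-count simulation hits its multinomial and dispersion limits", {
  bins <- data.frame(gene_id = "g", bin_id = c("b1", "b2"),
                     chrom = "c", strand = "+",
                     start = c(0L, 100L), end = c(100L, 300L),
                     source_transcripts = "x", ambiguous = FALSE)
  # dispersion 0: totals exactly baseline, proportions near widths (1:2)
  bc <- simulate_bin_counts(bins, samples_per_condition = 2,
                            baseline_depth = 3000, dispersion = 0, seed = 91)
  expect_true(all(colSums(bc$counts) == 3000))
  p_hat <- mean(bc$counts["b1", ] / 3000)
  expect_lt(abs(p_hat - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 3000))
  # planted shift moves condition B only
  eff <- data.frame(bin_id = "b1", log2_shift = 3)
  bc2 <- simulate_bin_counts(bins, samples_per_condition = 3,
                             baseline_depth = 2000, planted_effects = eff,
                             dispersion = 0, seed = 92)
  pA <- mean(bc2$counts["b1", bc2$condition == "A"]) / 2000
  pB <- mean(bc2$counts["b1", bc2$condition == "B"]) / 2000
  expect_lt(abs(pA - 1 / 3), 0.05)
  expect_lt(abs(pB - 8 / 10), 0.05)   # weight 8 vs 2 after the 2^3 shift
  expect_identical(bc2$counts,
                   simulate_bin_counts(bins, 3, 2000, eff, 0, seed = 92)$counts)
})
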