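test_that("constructed event patterns are classified by kind", {
  # ES: one internal exon absent
  ts_es <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 100), c(200, 300), c(400, 500))),
    b = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 100), c(400, 500)))))
  ev <- enumerate_events(ts_es)
  expect_equal(ev$kind, "ES")
  expect_equal(c(ev$var_start, ev$var_end), c(200L, 300L))
  expect_equal(ev$inclusion_ids, "a")
  expect_equal(ev$exclusion_ids, "b")

  # IR: variable region equals one intron of the exclusion isoform
  ts_ir <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 1000), c(1200, 1500))),
    b = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 1500)))))
  ev <- enumerate_events(ts_ir)
  expect_equal(ev$kind, "IR")
  expect_equal(c(ev$var_start, ev$var_end), c(1000L, 1200L))
  expect_equal(ev$exclusion_ids, "a")

  # ME: two consecutive internal exons absent
  ts_me <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 100), c(200, 250), c(300, 350), c(400, 500))),
    b = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 100), c(400, 500)))))
  expect_equal(enumerate_events(ts_me)$kind, "ME")

  # MX: exclusive internal exons, shared flanks
  ts_mx <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 100), c(200, 250), c(400, 500))),
    b = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 100), c(300, 350), c(400, 500)))))
  expect_equal(enumerate_events(ts_mx)$kind, "MX")

  # A5SS of 50 nt on the plus strand: introns (1000,2000) vs (1050,2000)
  ts_a5 <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 1000), c(2000, 2500))),
    b = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 1050), c(2000, 2500)))))
  ev <- enumerate_events(ts_a5)
  expect_equal(ev$kind, "A5SS")
  expect_equal(ev$var_end - ev$var_start, 50L)
  # same structure on minus strand is an A3SS (transcript orientation)
  ts_a3 <- make_ts(lapply(list(
    a = list(chrom = "c", strand = "-", gene = "g",
             exons = list(c(0, 1000), c(2000, 2500))),
    b = list(chrom = "c", strand = "-", gene = "g",
             exons = list(c(0, 1050), c(2000, 2500)))), identity))
  expect_equal(enumerate_events(ts_a3)$kind, "A3SS")

  # mixed strands at a locus are fatal
  ts_bad <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g", exons = list(c(0, 100), c(200, 300))),
    b = list(chrom = "c", strand = "-", gene = "g", exons = list(c(0, 100), c(200, 300)))))
  expect_error(enumerate_events(ts_bad), "mixed strands")
})

test_that("identical events from different pairs are merged once", {
  # three isoforms supporting the same IR
  ts <- make_ts(list(
    a = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 1000), c(1200, 1500))),
    a2 = list(chrom = "c", strand = "+", gene = "g",
              exons = list(c(100, 1000), c(1200, 1500))),
    b = list(chrom = "c", strand = "+", gene = "g",
             exons = list(c(0, 1500)))))
  ev <- enumerate_events(ts)
  ir <- ev[ev$kind == "IR", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$exclusion_ids, "a,a2")
  expect_equal(ir$n_pairs, 2L)
})

test_that("event enumeration equals the brute-force oracle on random loci", {
  for (seed in 1:60) {
    set.seed(seed)
    ts <- random_locus(n_iso = sample(2:6, 1), n_exons = sample(3:8, 1),
                       seed = seed + 1000)
    ev <- enumerate_events(ts, include_other = FALSE)
    orc <- oracle_events(ts)
    got <- sort(paste(ev$kind, ev$var_start, ev$var_end, ev$detail))
    want <- if (is.null(orc)) character() else
      sort(unique(paste(orc$kind, orc$var_start, orc$var_end, orc$detail)))
    expect_identical(got, want, label = paste("locus seed", seed))
  }
})

test_that("event sets are order-invariant and deduplication is idempotent", {
  ts <- random_locus(5, 7, seed = 77)
  ev <- enumerate_events(ts)
  ids <- rev(ts$transcripts$transcript_id)
  ts_r <- transcript_set(ts$exons, ts$transcripts[match(ids, ts$transcripts$transcript_id), ])
  ev_r <- enumerate_events(ts_r)
  expect_equal(ev[order(ev$kind, ev$var_start), c("kind", "var_start", "var_end")],
               ev_r[order(ev_r$kind, ev_r$var_start), c("kind", "var_start", "var_end")],
               ignore_attr = TRUE)
})

test_that("frequency table percentages are computed over the six kinds", {
  ev <- data.frame(kind = c("IR", "IR", "ES", "OTHER"), gene_id = "g",
                   chrom = "c", strand = "+", var_start = 1:4, var_end = 2:5,
                   inclusion_ids = "a", exclusion_ids = "b", n_pairs = 1)
  ft <- event_frequency_table(ev)
  expect_equal(ft$pct[ft$kind == "IR"], 200 / 3)
  expect_true(is.na(ft$pct[ft$kind == "OTHER"]))
  expect_equal(sum(ft$pct, na.rm = TRUE), 100)
  expect_equal(nrow(event_frequency_table(ev[0, ])), 0L)
})

test_that("tissue-specific calls follow the eight-fold + adjusted-p rule", {
  set.seed(8)
  n_ev <- 40
  tissues <- paste0("T", 1:4)
  gene_tot <- matrix(2000L, n_ev, 4, dimnames = list(paste0("e", 1:n_ev), tissues))
  counts <- matrix(rpois(n_ev * 4, 50), n_ev, 4,
                   dimnames = dimnames(gene_tot))
  # event 1: 16-fold enrichment in T1
  counts[1, ] <- c(800L, 50L, 50L, 50L)
  res <- tissue_specific_events(counts, gene_tot)
  r1 <- res[res$event_id == "e1" & res$tissue == "T1", ]
  expect_true(r1$tissue_specific)
  expect_gt(r1$log2_fc, 3)
  expect_lt(r1$adj_p_value, 0.05)
  # flat events are not specific and have ~zero fold-change
  flat <- res[res$event_id != "e1", ]
  expect_lt(mean(flat$tissue_specific), 0.05)
  expect_true(all(res$adj_p_value >= res$p_value - 1e-12))
  # identical normalized counts -> log2_fc exactly 0
  eq <- matrix(60L, 2, 4, dimnames = list(c("a", "b"), tissues))
  res_eq <- tissue_specific_events(eq, matrix(600L, 2, 4, dimnames = dimnames(eq)))
  expect_true(all(res_eq$log2_fc == 0))
  expect_false(any(res_eq$tissue_specific))
  # degenerate zero gene totals are skipped
  gt0 <- gene_tot; gt0[2, 1] <- 0L
  expect_message(res0 <- tissue_specific_events(counts, gt0), "skipped")
  expect_false(any(res0$event_id == "e2" & res0$tissue == "T1"))
})
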