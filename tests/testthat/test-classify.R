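test_that("junction typing is strand-aware and looks up the annotated set", {
  # plus intron (10,20) with GT..AG; minus intron (40,50) with CT..AC
  chr <- paste0(strrep("A", 10), "GT", strrep("C", 6), "AG",
                strrep("A", 10), "CT", strrep("C", 6), "AC", strrep("A", 10))
  g <- make_genome(chr1 = chr)
  ts <- make_ts(list(
    p = list(chrom = "chr1", strand = "+", exons = list(c(0, 10), c(20, 30)), gene = "gp"),
    m = list(chrom = "chr1", strand = "-", exons = list(c(20, 30), c(40, 50)), gene = "gm")))
  ann <- annotation_index(ts)
  jx <- classify_junctions(ts, g, ann)
  expect_true(all(jx$canonical))
  expect_true(all(jx$known))
  expect_equal(jx$donor[jx$transcript_id == "m"], "GT")
  expect_equal(jx$acceptor[jx$transcript_id == "m"], "AG")

  # GG..AG is non-canonical
  chr2 <- paste0(strrep("A", 10), "GG", strrep("C", 6), "AG", strrep("A", 10))
  ts2 <- make_ts(list(p = list(chrom = "chr1", strand = "+",
                               exons = list(c(0, 10), c(20, 30)), gene = "g")))
  jx2 <- classify_junctions(ts2, make_genome(chr1 = chr2), ann = NULL)
  expect_false(jx2$canonical)

  # intron past the chromosome end is fatal
  ts3 <- make_ts(list(p = list(chrom = "chr1", strand = "+",
                               exons = list(c(0, 10), c(29, 33)))))
  expect_error(classify_junctions(ts3, make_genome(chr1 = "ACGTACGTACGTACGTACGTACGTACG"), NULL),
               "past chromosome end")
})

test_that("terminal distances are signed in transcript orientation", {
  ref <- data.frame(transcript_id = "r", chrom = "c", strand = "+",
                    start = 1000, end = 5000)
  mod <- ref; mod$start <- 1150
  expect_equal(terminal_distances(mod, ref), c(dist5 = 150, dist3 = 0))
  ref$strand <- mod$strand <- "-"
  mod$start <- 1000; mod$end <- 5030
  expect_equal(terminal_distances(mod, ref), c(dist5 = -30, dist3 = 0))
  mod$strand <- "+"
  expect_error(terminal_distances(mod, ref), "different chrom/strand")
})

test_that("hand-built models hit their expected structural categories", {
  ts_ref <- make_ts(list(
    t1 = list(chrom = "c1", strand = "+", gene = "g1",
              exons = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800), c(900, 1000))),
    t2 = list(chrom = "c1", strand = "+", gene = "g2",
              exons = list(c(5000, 5200), c(5400, 5600))),
    t3 = list(chrom = "c1", strand = "-", gene = "g3",
              exons = list(c(8000, 8900)))))
  ann <- annotation_index(ts_ref)
  cl <- function(spec) classify_transcripts(make_ts(spec), ann)
  one <- function(spec) cl(spec)$category

  # FSM with matched id and zero distances
  full <- cl(list(m = list(chrom = "c1", strand = "+",
                           exons = list(c(100, 200), c(300, 400), c(500, 600),
                                        c(700, 800), c(900, 1000)))))
  expect_equal(full$category, "FSM")
  expect_equal(full$matched_transcript_id, "t1")
  expect_equal(c(full$dist5, full$dist3), c(0, 0))

  # last-2-introns sub-chain -> ISM
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(550, 600), c(700, 800), c(900, 1000))))),
               "ISM")
  # exon skip re-pairing annotated sites -> NIC
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(100, 200), c(300, 400), c(700, 800), c(900, 1000))))),
               "NIC")
  # unannotated donor + exonic overlap -> NNC
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(100, 230), c(300, 400), c(500, 600))))),
               "NNC")
  # junctions of two separated genes -> FUSION
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(700, 800), c(900, 1000), c(5100, 5200), c(5400, 5500))))),
               "FUSION")
  # mono-exon inside an intron, same strand -> GENIC_INTRON
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(420, 480))))),
               "GENIC_INTRON")
  # exon/intron straddle -> GENIC_GENOMIC
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(150, 250))))),
               "GENIC_GENOMIC")
  # only opposite-strand overlap -> ANTISENSE
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(8100, 8300))))),
               "ANTISENSE")
  # far away -> INTERGENIC
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(20000, 20500))))),
               "INTERGENIC")
  # mono-exon inside a mono-exon reference exon, ends within 100 nt -> FSM
  expect_equal(one(list(m = list(chrom = "c1", strand = "-",
                                 exons = list(c(8050, 8850))))),
               "FSM")
  # mono-exon inside a multi-exon reference exon -> ISM
  expect_equal(one(list(m = list(chrom = "c1", strand = "+",
                                 exons = list(c(120, 180))))),
               "ISM")
})

test_that("classification agrees with the brute-force oracle on random models", {
  g <- simulate_genome(1, 8e5, 0.4, seed = 31)
  sim <- simulate_annotation(g, n_genes = 40, seed = 31)
  models <- random_models(sim, 300, seed = 32)
  ann <- annotation_index(sim$models)
  calls <- classify_transcripts(models, ann)
  oref <- oracle_ref(sim$models)
  expected <- vapply(calls$transcript_id, function(id)
    oracle_classify(exons_of(models, id), oref), character(1))
  expect_equal(calls$category, unname(expected))
})

test_that("clean annotation copies classify FSM with zero terminal distances", {
  g <- simulate_genome(1, 4e5, 0.4, seed = 33)
  sim <- simulate_annotation(g, n_genes = 20, seed = 33)
  ann <- annotation_index(sim$models)
  calls <- classify_transcripts(sim$models, ann, sim$genome)
  expect_true(all(calls$category == "FSM"))
  expect_true(all(calls$dist5 == 0 & calls$dist3 == 0))
  expect_true(all(calls$n_known == calls$n_junctions))

  s <- summarize_categories(calls, sim$models, ann)
  expect_equal(sum(s$categories$fraction), 1)
  expect_equal(s$categories$count[s$categories$category == "FSM"], length(sim$models))
  expect_equal(s$n_novel_genes, 0L)
})

test_that("novel genes are clustered by exonic overlap", {
  ts_ref <- make_ts(list(t1 = list(chrom = "c1", strand = "+", gene = "g1",
                                   exons = list(c(100, 200), c(300, 400)))))
  ann <- annotation_index(ts_ref)
  models <- make_ts(list(
    n1 = list(chrom = "c1", strand = "+", exons = list(c(10000, 10500))),
    n2 = list(chrom = "c1", strand = "+", exons = list(c(10400, 10900))),
    n3 = list(chrom = "c1", strand = "+", exons = list(c(30000, 30400)))))
  calls <- classify_transcripts(models, ann)
  s <- summarize_categories(calls, models, ann)
  expect_equal(s$n_novel_genes, 2L)    # n1+n2 overlap -> one novel gene
})
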