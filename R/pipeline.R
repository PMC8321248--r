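#' Run the full isoform characterization pipeline
#'
#' Executes the stages in order — quality filter + collapse, structural
#' classification, artifact filtration, AS-event enumeration, polyA/ORF
#' analysis — over aligned read models, a genome and a reference annotation,
#' writing stage outputs and a summary JSON under `out_dir`. Stages are
#' skippable by flag; the differential exon-usage stage runs only when bin
#' counts and a condition vector are supplied.
#'
#' @param reads a `transcript_set` of aligned read models
#' @param genome genome from [read_genome()]
#' @param reference a `transcript_set` of reference transcripts (with gene ids)
#' @param junction_table optional junction support table
#' @param out_dir output directory (created)
#' @param config list of thresholds overriding the defaults:
#'   min_identity (0.95), min_coverage (0.99), tol3 (100), a_threshold (0.6),
#'   rts_k (8), min_unique (1), min_orf_aa (100), pas_window (50),
#'   noncoding_min_len (200)
#' @param stages character subset of c("collapse","classify","filter",
#'   "events","polya_orf") to run (default all)
#' @param usage optional list(counts, bins, condition) for the exon-usage stage
#' @return list with each stage's result and `summary` (also written as
#'   summary.json)
#' @export
run_pipeline <- function(reads, genome, reference, junction_table = NULL,
                         out_dir = tempfile("isoscan_run_"), config = list(),
                         stages = c("collapse", "classify", "filter",
                                    "events", "polya_orf"),
                         usage = NULL) {
  cfg <- utils::modifyList(list(
    min_identity = 0.95, min_coverage = 0.99, tol3 = 100L,
    a_threshold = 0.6, rts_k = 8L, min_unique = 1L,
    min_orf_aa = 100L, pas_window = 50L, noncoding_min_len = 200L), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- annotation_index(reference)
  res <- list(config = cfg, out_dir = out_dir)
  summary <- list(n_input_reads = length(reads))

  isoforms <- reads
  if ("collapse" %in% stages) {
    fq <- filter_alignment_quality(reads, cfg$min_identity, cfg$min_coverage)
    cr <- collapse_isoforms(fq$models, tol3 = cfg$tol3)
    cr$dropped_low_quality <- fq$dropped_low_quality
    isoforms <- cr$isoforms
    res$collapse <- cr
    write_gtf(isoforms, file.path(out_dir, "isoforms.gtf"))
    utils::write.table(cr$membership, file.path(out_dir, "membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_dropped_low_quality <- length(fq$dropped_low_quality)
    summary$n_isoforms <- length(isoforms)
  }

  calls <- NULL
  if ("classify" %in% stages) {
    calls <- classify_transcripts(isoforms, ann, genome)
    res$classification <- calls
    utils::write.table(calls, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cat_sum <- summarize_categories(calls, isoforms, ann)
    res$category_summary <- cat_sum
    summary$categories <- stats::setNames(as.list(cat_sum$categories$count),
                                          cat_sum$categories$category)
    summary$n_known_genes <- cat_sum$n_known_genes
    summary$n_novel_genes <- cat_sum$n_novel_genes
    jx <- classify_junctions(isoforms, genome, ann)
    res$junctions <- jx
    summary$junctions <- list(
      n = nrow(jx),
      known_canonical = sum(jx$known & jx$canonical),
      known_noncanonical = sum(jx$known & !jx$canonical),
      novel_canonical = sum(!jx$known & jx$canonical),
      novel_noncanonical = sum(!jx$known & !jx$canonical))
  }

  if ("filter" %in% stages) {
    fr <- filter_isoforms(isoforms, genome, ann, junction_table, calls,
                          a_threshold = cfg$a_threshold, k = cfg$rts_k,
                          min_unique = cfg$min_unique)
    res$filter <- fr
    utils::write.table(fr$report, file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    isoforms <- fr$kept
    write_gtf(isoforms, file.path(out_dir, "isoforms_filtered.gtf"))
    removed <- fr$report[fr$report$disposition == "removed", ]
    summary$n_removed <- nrow(removed)
    summary$removal_reasons <- as.list(table(removed$reason))
    if (!is.null(calls))
      calls <- calls[calls$transcript_id %in% isoforms$transcripts$transcript_id, ]
  }

  if ("events" %in% stages) {
    ev_models <- isoforms
    if (any(is.na(ev_models$transcripts$gene_id))) {
      # assign classification-derived gene ids where available
      if (!is.null(calls)) {
        g <- sub(",.*$", "", calls$associated_genes)
        g[g == ""] <- paste0("novel_", calls$transcript_id[g == ""])
        ev_models$transcripts$gene_id <-
          g[match(ev_models$transcripts$transcript_id, calls$transcript_id)]
      }
    }
    ev <- enumerate_events(ev_models)
    res$events <- ev
    freq <- event_frequency_table(ev)
    res$event_frequency <- freq
    utils::write.table(ev, file.path(out_dir, "as_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$as_events <- stats::setNames(as.list(freq$count), freq$kind)
  }

  if ("polya_orf" %in% stages) {
    pas <- scan_polya_signals(isoforms, genome, window = cfg$pas_window)
    res$pas <- pas
    orfs <- call_orfs(isoforms, genome, min_aa = cfg$min_orf_aa)
    nc <- flag_noncoding(isoforms, orfs, min_aa = cfg$min_orf_aa,
                         min_len = cfg$noncoding_min_len)
    res$orfs <- orfs; res$noncoding <- nc
    utils::write.table(pas$hits, file.path(out_dir, "pas_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nc, file.path(out_dir, "coding_class.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(orfs, file.path(out_dir, "orf_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    called <- orfs[!is.na(orfs$aa_length), , drop = FALSE]
    if (nrow(called)) {
      seqs <- spliced_sequence(isoforms, genome, called$transcript_id)
      prot <- vapply(seq_len(nrow(called)), function(i) {
        cds <- substr(seqs[[i]], called$orf_start[i] + 1L, called$orf_end[i])
        cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
        as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
      }, character(1L))
      aa <- Biostrings::AAStringSet(sub("\\*$", "", prot))
      names(aa) <- called$transcript_id
      Biostrings::writeXStringSet(aa, file.path(out_dir, "orf_proteins.fa"))
    }
    summary$pas_motifs <- stats::setNames(as.list(pas$motif_frequency$count),
                                          pas$motif_frequency$motif)
    summary$n_orfs <- sum(!is.na(orfs$aa_length))
    summary$n_noncoding <- sum(nc$class == "noncoding")
  }

  if (!is.null(usage)) {
    du <- differential_usage(usage$counts, usage$bins, usage$condition)
    res$usage <- du
    utils::write.table(du, file.path(out_dir, "usage_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_usage_hits <- sum(du$adj_p_value < 0.05, na.rm = TRUE)
  }

  res$summary <- summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}
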