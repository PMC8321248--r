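#' Genomic adenine fraction downstream of a model's 3' end
#'
#' Fraction of A in the `window` genomic nt immediately 3' of the isoform's
#' terminal position, read in transcript orientation (on the minus strand the
#' genomic window lies upstream in genomic coordinates and is
#' reverse-complemented, so genomic T reads as A). A high fraction marks
#' likely oligo(dT) intrapriming at a genomic A-tract rather than a true
#' polyA tail. The window is truncated at the chromosome edge.
#'
#' @param models a `transcript_set`
#' @param genome genome from [read_genome()]
#' @param window nt downstream of the TTS to inspect (default 20)
#' @return named numeric vector (one value per transcript, in \[0,1\])
#' @export
intrapriming_fraction <- function(models, genome, window = 20L) {
  tt <- tx_table(models)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  vapply(seq_len(nrow(tt)), function(i) {
    if (tt$strand[i] == "+") {
      s <- tt$end[i]; e <- min(tt$end[i] + window, chrom_len[[tt$chrom[i]]])
    } else {
      s <- max(tt$start[i] - window, 0L); e <- tt$start[i]
    }
    if (s >= e) return(0)
    seq <- fetch_sequence(genome, tt$chrom[i], s, e, tt$strand[i])
    ch <- strsplit(seq, "")[[1L]]
    sum(ch == "A") / length(ch)
  }, numeric(1L), USE.NAMES = FALSE) -> fr
  stats::setNames(fr, tt$transcript_id)
}

#' Flag reverse-transcriptase template-switch candidate junctions
#'
#' RT switching leaves an exact direct repeat shared between the last `k`
#' exonic nt at the donor boundary and the `k` nt ending at the acceptor
#' boundary inside the intron (both read in transcript orientation). A
#' junction is flagged when those two k-mers are identical.
#'
#' @param junctions data.frame with chrom, strand, start, end (0-based
#'   half-open introns)
#' @param genome genome from [read_genome()]
#' @param k repeat length (default 8; exact match only)
#' @return logical vector, one per junction row
#' @export
rt_switching_flag <- function(junctions, genome, k = 8L) {
  vapply(seq_len(nrow(junctions)), function(i) {
    ch <- junctions$chrom[i]; s <- junctions$start[i]; e <- junctions$end[i]
    L <- length(genome[[ch]])
    if (junctions$strand[i] == "+") {
      if (s < k || e - s < k) return(FALSE)
      donor_kmer <- fetch_sequence(genome, ch, s - k, s)
      acceptor_kmer <- fetch_sequence(genome, ch, e - k, e)
    } else {
      if (e + k > L || e - s < k) return(FALSE)
      donor_kmer <- fetch_sequence(genome, ch, e, e + k, "-")
      acceptor_kmer <- fetch_sequence(genome, ch, s, s + k, "-")
    }
    identical(donor_kmer, acceptor_kmer)
  }, logical(1L))
}

#' Compose the artifact filters over a classified isoform set
#'
#' An isoform is removed when any rule fails: (a) intrapriming — downstream
#' A-fraction at or above `a_threshold`; (b) RT switching — any junction
#' flagged by [rt_switching_flag()]; (c) short-read support — the isoform
#' carries a novel junction whose unique-read support in the junction table
#' is below `min_unique` (FSM isoforms are exempt from this rule: all their
#' junctions are annotated by definition). A strand-undefined table row
#' supports a junction on either strand. Without a junction table the
#' support rule is skipped with a warning.
#'
#' @param models a `transcript_set`
#' @param genome genome from [read_genome()]
#' @param ann an `annotation_index` (used for novel-junction status)
#' @param junction_table data.frame from [read_junction_table()], or NULL
#' @param calls optional classification table from [classify_transcripts()]
#'   (identifies FSM isoforms; when absent, FSM status is derived from the
#'   junction set)
#' @param a_threshold intrapriming A-fraction cut-off (default 0.6)
#' @param k RT-switch repeat length (default 8)
#' @param min_unique minimum unique-read support for novel junctions (default 1)
#' @param window intrapriming window (default 20)
#' @return list of class `filter_report`: `report` (data.frame isoform_id,
#'   a_fraction, intrapriming, rts_flag, n_unsupported, disposition, reason),
#'   `kept` (a `transcript_set`)
#' @export
filter_isoforms <- function(models, genome, ann, junction_table = NULL,
                            calls = NULL, a_threshold = 0.6, k = 8L,
                            min_unique = 1L, window = 20L) {
  tt <- tx_table(models)
  afrac <- intrapriming_fraction(models, genome, window)
  jx <- classify_junctions(models, genome, ann)
  rts_by_tx <- rep(FALSE, nrow(tt)); names(rts_by_tx) <- tt$transcript_id
  if (nrow(jx)) {
    jx$rts <- rt_switching_flag(jx, genome, k)
    agg <- tapply(jx$rts, jx$transcript_id, any)
    rts_by_tx[names(agg)] <- agg
  }

  n_unsup <- rep(0L, nrow(tt)); names(n_unsup) <- tt$transcript_id
  if (is.null(junction_table)) {
    warning("no junction table supplied; short-read support filter skipped")
  } else if (nrow(jx)) {
    sup_key <- paste(junction_table$chrom, junction_table$strand,
                     junction_table$start, junction_table$end)
    sup_any <- paste(junction_table$chrom, "*",
                     junction_table$start, junction_table$end)
    lookup <- function(chrom, strand, s, e) {
      i <- match(paste(chrom, strand, s, e), sup_key)
      if (!is.na(i)) return(junction_table$unique_read_support[i])
      i <- match(paste(chrom, "*", s, e), sup_any)
      if (!is.na(i)) return(junction_table$unique_read_support[i])
      0L
    }
    if (!is.null(calls)) {
      fsm_ids <- calls$transcript_id[calls$category == "FSM"]
    } else {
      all_known <- tapply(jx$known, jx$transcript_id, all)
      fsm_ids <- names(all_known)[all_known]
    }
    novel <- jx[!jx$known & !jx$transcript_id %in% fsm_ids, , drop = FALSE]
    if (nrow(novel)) {
      unsup <- vapply(seq_len(nrow(novel)), function(i)
        lookup(novel$chrom[i], novel$strand[i], novel$start[i], novel$end[i]) < min_unique,
        logical(1L))
      agg <- tapply(unsup, novel$transcript_id, sum)
      n_unsup[names(agg)] <- as.integer(agg)
    }
  }

  intraprime <- afrac >= a_threshold
  removed <- intraprime | rts_by_tx | n_unsup > 0L
  reason <- vapply(seq_len(nrow(tt)), function(i) {
    why <- c(if (intraprime[i]) "intrapriming",
             if (rts_by_tx[i]) "rt_switching",
             if (n_unsup[i] > 0L) "unsupported_junction")
    if (length(why)) paste(why, collapse = ";") else ""
  }, character(1L))

  report <- data.frame(
    isoform_id = tt$transcript_id,
    a_fraction = unname(afrac),
    intrapriming = unname(intraprime),
    rts_flag = unname(rts_by_tx),
    n_unsupported = unname(n_unsup),
    disposition = ifelse(removed, "removed", "kept"),
    reason = reason, stringsAsFactors = FALSE)
  structure(list(report = report,
                 kept = subset_transcripts(models, tt$transcript_id[!removed])),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d isoforms, %d removed (%s)\n",
              nrow(x$report), sum(x$report$disposition == "removed"),
              paste(names(table(x$report$reason[x$report$reason != ""])),
                    collapse = ", ")))
  invisible(x)
}
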