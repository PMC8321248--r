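#' Default polyadenylation-signal hexamers
#'
#' The canonical AATAAA and ATTAAA plus ten common single-substitution
#' variants reported across vertebrate 3'-end studies.
#' @export
PAS_MOTIFS <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
                "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")

#' Scan for polyadenylation signals upstream of isoform 3' ends
#'
#' The transcript-orientation 3'-terminal `window` nt of each spliced isoform
#' sequence are scanned for the motif list; the hit closest to the cleavage
#' site is the primary call. Distance is counted from the motif start to the
#' cleavage site (the 3' end), so a motif whose start is the 16th nt from the
#' end has distance 16.
#'
#' @param models a `transcript_set`
#' @param genome genome from [read_genome()]
#' @param motifs character vector of hexamers (default [PAS_MOTIFS])
#' @param window nt upstream of the cleavage site to scan (default 50);
#'   isoforms shorter than the window are scanned over their full length
#' @return list: `hits` (data.frame transcript_id, motif, distance; one
#'   primary call per isoform with a hit), `motif_frequency` (data.frame
#'   motif, count, fraction over isoforms with >= 1 hit), `n_no_hit`
#' @export
scan_polya_signals <- function(models, genome, motifs = PAS_MOTIFS, window = 50L) {
  stopifnot(length(motifs) > 0L)
  seqs <- spliced_sequence(models, genome)
  rows <- list(); n_no_hit <- 0L
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    tail_seq <- substr(s, max(1L, L - window + 1L), L)
    TL <- nchar(tail_seq)
    if (TL < 6L) { n_no_hit <- n_no_hit + 1L; next }
    # every window position (overlapping occurrences included)
    subs <- substring(tail_seq, seq_len(TL - 5L), seq_len(TL - 5L) + 5L)
    hit <- which(subs %in% motifs)
    if (!length(hit)) { n_no_hit <- n_no_hit + 1L; next }
    pos <- max(hit)                     # closest to the cleavage site
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = id, motif = subs[pos], distance = TL - pos + 1L,
      stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), motif = character(),
               distance = integer(), stringsAsFactors = FALSE)
  freq <- if (nrow(hits)) {
    cnt <- sort(table(hits$motif), decreasing = TRUE)
    data.frame(motif = names(cnt), count = as.integer(cnt),
               fraction = as.numeric(cnt) / nrow(hits), stringsAsFactors = FALSE)
  } else data.frame(motif = character(), count = integer(), fraction = numeric(),
                    stringsAsFactors = FALSE)
  list(hits = hits, motif_frequency = freq, n_no_hit = n_no_hit)
}

#' Longest open reading frame in a transcript sequence
#'
#' Scans the three forward frames for ATG...stop ORFs (stops TAA/TAG/TGA);
#' a 3'-partial ORF running off the sequence end without a stop is admitted
#' and marked `has_stop = FALSE`. Returns the longest ORF by amino-acid
#' length (codons excluding the stop) when it reaches `min_aa`, else NULL.
#' Ties go to the leftmost start.
#'
#' @param seq character scalar (spliced, strand-corrected transcript sequence)
#' @param min_aa minimum ORF length in amino acids (default 100)
#' @return NULL, or list(start, end, frame, aa_length, has_stop) with
#'   0-based half-open coordinates into `seq` (end excludes a partial codon;
#'   includes the stop codon when present)
#' @export
longest_orf <- function(seq, min_aa = 100L) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    i <- frame + 1L
    orf_start <- NA_integer_
    while (i + 2L <= L) {
      codon <- substr(seq, i, i + 2L)
      if (is.na(orf_start)) {
        if (codon == "ATG") orf_start <- i
      } else if (codon %in% stops) {
        aa <- (i - orf_start) %/% 3L
        cand <- list(start = orf_start - 1L, end = i + 2L, frame = frame,
                     aa_length = aa, has_stop = TRUE)
        if (is.null(best) || aa > best$aa_length ||
            (aa == best$aa_length && cand$start < best$start)) best <- cand
        orf_start <- NA_integer_
      }
      i <- i + 3L
    }
    if (!is.na(orf_start)) {          # 3'-partial ORF, no stop reached
      aa <- (i - orf_start) %/% 3L
      cand <- list(start = orf_start - 1L, end = orf_start - 1L + 3L * aa,
                   frame = frame, aa_length = aa, has_stop = FALSE)
      if (is.null(best) || aa > best$aa_length ||
          (aa == best$aa_length && cand$start < best$start)) best <- cand
    }
  }
  if (is.null(best) || best$aa_length < min_aa) return(NULL)
  best
}

#' ORF calls for every model
#' @param models a `transcript_set`
#' @param genome genome from [read_genome()]
#' @param min_aa minimum ORF length (default 100)
#' @return data.frame: transcript_id, orf_start, orf_end, frame, aa_length,
#'   has_stop; one row per model, NA fields when no qualifying ORF
#' @export
call_orfs <- function(models, genome, min_aa = 100L) {
  seqs <- spliced_sequence(models, genome)
  rows <- lapply(names(seqs), function(id) {
    o <- longest_orf(seqs[[id]], min_aa)
    if (is.null(o))
      data.frame(transcript_id = id, orf_start = NA_integer_, orf_end = NA_integer_,
                 frame = NA_integer_, aa_length = NA_integer_, has_stop = NA,
                 stringsAsFactors = FALSE)
    else
      data.frame(transcript_id = id, orf_start = o$start, orf_end = o$end,
                 frame = o$frame, aa_length = o$aa_length, has_stop = o$has_stop,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag putative non-coding transcripts
#'
#' A transcript is a putative non-coding candidate when it harbors no ORF of
#' at least `min_aa` amino acids and its spliced length exceeds `min_len` nt;
#' ORF-less transcripts at or below the length gate are labeled
#' short/unclassified.
#'
#' @param models a `transcript_set`
#' @param orf_calls output of [call_orfs()]
#' @param min_aa coding ORF threshold in aa (default 100)
#' @param min_len non-coding length gate in nt (default 200; strictly greater
#'   qualifies)
#' @return data.frame: transcript_id, spliced_len, aa_length, class in
#'   {coding, noncoding, short_unclassified}
#' @export
flag_noncoding <- function(models, orf_calls, min_aa = 100L, min_len = 200L) {
  tt <- tx_table(models)
  aa <- orf_calls$aa_length[match(tt$transcript_id, orf_calls$transcript_id)]
  cls <- ifelse(!is.na(aa) & aa >= min_aa, "coding",
                ifelse(tt$exonic_len > min_len, "noncoding", "short_unclassified"))
  data.frame(transcript_id = tt$transcript_id, spliced_len = tt$exonic_len,
             aa_length = aa, class = cls, stringsAsFactors = FALSE)
}
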