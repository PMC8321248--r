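#' Load a genome from FASTA
#'
#' @param path FASTA file with unique headers
#' @return a `DNAStringSet` keyed by chromosome (first word of each header)
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  bad <- Biostrings::alphabetFrequency(g, baseOnly = TRUE)[, "other"]
  if (any(bad > 0))
    warning("non-ACGTN symbols present in: ",
            paste(names(g)[bad > 0], collapse = ", "), " (preserved)")
  g
}

#' Fetch a genomic subsequence
#'
#' Half-open 0-based coordinates; `strand = "-"` returns the reverse
#' complement (i.e. the sequence in transcript orientation).
#' @param genome a `DNAStringSet` from [read_genome()]
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @param strand "+" or "-"
#' @return character scalar
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- length(genome[[chrom]])
  if (start < 0 || end > L || start >= end)
    stop(sprintf("invalid interval %s:%d-%d (chromosome length %d)", chrom, start, end, L))
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#' @param s character scalar
#' @return character scalar
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read a GTF/GFF3 annotation into a transcript_set
#'
#' File coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention. Exon rows are grouped per transcript; a GFF3
#' exon's `Parent` is its transcript and the transcript's `Parent` its gene.
#'
#' @param path GTF or GFF3 file
#' @param dialect "auto" (by extension), "gtf" or "gff3"
#' @return a `transcript_set`
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  n_lines <- length(readLines(path, n = 5000L))
  if (n_lines == 0L || all(grepl("^\\s*(#|$)", readLines(path))))
    return(transcript_set(
      data.frame(transcript_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character()),
      data.frame(transcript_id = character(), gene_id = character())))
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (dialect == "gtf") {
    tx_id <- as.character(ex$transcript_id)
    gene_id <- as.character(ex$gene_id)
  } else {
    parent <- as.character(S4Vectors::unlist(ex$Parent))
    tx_id <- sub("^transcript:", "", parent)
    # map transcript -> gene through transcript-level rows
    lvl <- gr[tolower(as.character(gr$type)) %in%
                c("mrna", "transcript", "lnc_rna", "ncrna")]
    g_of <- sub("^gene:", "", as.character(S4Vectors::unlist(lvl$Parent)))
    names(g_of) <- sub("^transcript:", "", as.character(lvl$ID))
    gene_id <- unname(g_of[tx_id])
  }
  if (any(is.na(tx_id)) || any(tx_id == ""))
    stop("exon row without transcript_id in ", path)
  exons <- data.frame(
    transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  if (any(exons$strand == "*"))
    stop("exon rows without strand in ", path)
  tx <- unique(data.frame(transcript_id = tx_id, gene_id = gene_id,
                          stringsAsFactors = FALSE))
  if (anyDuplicated(tx$transcript_id))
    stop("transcript(s) assigned to multiple genes: ",
         paste(tx$transcript_id[duplicated(tx$transcript_id)], collapse = ", "))
  mixed <- tapply(exons$strand, exons$transcript_id, function(s) length(unique(s)))
  if (any(mixed > 1L))
    stop("transcript with exons on mixed strands: ",
         paste(names(mixed)[mixed > 1L], collapse = ", "))
  transcript_set(exons, tx)
}

#' Write a transcript_set as GTF
#'
#' Emits transcript and exon rows with `gene_id`/`transcript_id` attributes;
#' internal 0-based half-open coordinates become 1-based inclusive.
#' @param x a `transcript_set`
#' @param path output file
#' @param source source field for column 2
#' @return invisibly, `path`
#' @export
write_gtf <- function(x, path, source = "isoscan") {
  tt <- tx_table(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tt))) {
    id <- tt$transcript_id[i]
    gid <- if (is.na(tt$gene_id[i])) id else tt$gene_id[i]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, id)
    writeLines(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tt$chrom[i], source, tt$start[i] + 1L, tt$end[i],
                       tt$strand[i], attrs), con)
    r <- exons_of(x, id)
    writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                       r$chrom, source, r$start + 1L, r$end, r$strand, attrs), con)
  }
  invisible(path)
}

#' Read exon chains from BED12
#'
#' @param path BED12 file (blockSizes/blockStarts define the exon chain)
#' @return a `transcript_set` (gene ids absent)
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  ids <- as.character(gr$name)
  if (anyDuplicated(ids)) stop("duplicate BED names in ", path)
  blocks <- gr$blocks
  rows <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    data.frame(transcript_id = ids[i],
               chrom = as.character(GenomicRanges::seqnames(gr[i])),
               start = GenomicRanges::start(gr[i]) - 1L + (GenomicRanges::start(b) - 1L),
               end = GenomicRanges::start(gr[i]) - 1L + GenomicRanges::end(b),
               strand = as.character(GenomicRanges::strand(gr[i])),
               stringsAsFactors = FALSE)
  })
  transcript_set(do.call(rbind, rows))
}

#' Write exon chains as BED12
#' @param x a `transcript_set`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_bed12 <- function(x, path) {
  tt <- tx_table(x)
  lines <- vapply(seq_len(nrow(tt)), function(i) {
    r <- exons_of(x, tt$transcript_id[i])
    sizes <- paste0(paste(r$end - r$start, collapse = ","), ",")
    starts <- paste0(paste(r$start - tt$start[i], collapse = ","), ",")
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            tt$chrom[i], tt$start[i], tt$end[i], tt$transcript_id[i],
            tt$strand[i], tt$start[i], tt$end[i], nrow(r), sizes, starts)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a splice-junction table (SJ.out.tab dialect)
#'
#' Nine tab-separated columns: chrom, 1-based intron start, 1-based inclusive
#' intron end, strand code (0 undefined / 1 plus / 2 minus), motif code,
#' annotated flag, unique reads, multimapping reads, max overhang. Introns
#' are stored 0-based half-open; duplicate intron rows have their unique-read
#' supports summed. Malformed rows are skipped with a message naming the line.
#'
#' @param path SJ.out.tab-style file
#' @return data.frame: chrom, start, end, strand ("+", "-", or "*" for
#'   undefined), unique_read_support
#' @export
read_junction_table <- function(path) {
  raw <- readLines(path)
  recs <- list()
  for (i in seq_along(raw)) {
    if (grepl("^\\s*(#|$)", raw[i])) next
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1L]]
    ok <- length(f) >= 7L && !is.na(suppressWarnings(as.integer(f[2L]))) &&
      !is.na(suppressWarnings(as.integer(f[3L]))) &&
      !is.na(suppressWarnings(as.integer(f[7L])))
    if (!ok) { message("read_junction_table: skipping malformed line ", i); next }
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = f[1L],
      start = as.integer(f[2L]) - 1L,
      end = as.integer(f[3L]),
      strand = c("*", "+", "-")[as.integer(f[4L]) + 1L],
      unique_read_support = as.integer(f[7L]),
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), unique_read_support = integer(),
                      stringsAsFactors = FALSE))
  jt <- do.call(rbind, recs)
  key <- paste(jt$chrom, jt$start, jt$end, jt$strand)
  agg <- rowsum(jt$unique_read_support, key)
  jt <- jt[!duplicated(key), , drop = FALSE]
  jt$unique_read_support <- as.integer(agg[match(paste(jt$chrom, jt$start, jt$end, jt$strand),
                                                 rownames(agg)), 1L])
  rownames(jt) <- NULL
  jt
}

#' Write a junction table in the SJ.out.tab dialect
#' @param junctions data.frame as produced by [read_junction_table()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_junction_table <- function(junctions, path) {
  code <- match(junctions$strand, c("*", "+", "-")) - 1L
  writeLines(sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t0",
                     junctions$chrom, junctions$start + 1L, junctions$end,
                     code, junctions$unique_read_support), path)
  invisible(path)
}

# Walk a CIGAR string along the reference, returning exon blocks and the
# numbers needed for identity/coverage.
parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  list(n = n, op = op)
}

#' Extract exon chains from a SAM file
#'
#' Minimal read-only ingestion of spliced alignments: M/=/X/D consume the
#' reference into exons, N splits exons, S/I consume only the query.
#' Identity is (aligned query bases - NM edits) / aligned query bases when an
#' NM tag is present (else NA); coverage is the aligned fraction of the query
#' (soft and hard clips excluded). Unmapped records are skipped and counted.
#'
#' @param path SAM text file
#' @return list: `models` (a `transcript_set` with `identity` and `coverage`
#'   columns on its transcript table) and `n_unmapped`
#' @export
read_sam_exon_chains <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines)]
  exon_rows <- list(); tx_rows <- list(); n_unmapped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L || f[6L] == "*") { n_unmapped <- n_unmapped + 1L; next }
    pos <- as.integer(f[4L]) - 1L      # 0-based
    cig <- parse_cigar(f[6L])
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    ref <- pos; ex_start <- pos
    exs <- list(); qlen_aln <- 0L; qlen_clip <- 0L; ins <- 0L; del <- 0L
    for (i in seq_along(cig$n)) {
      k <- cig$n[i]
      switch(cig$op[i],
             "M" = , "=" = , "X" = { ref <- ref + k; qlen_aln <- qlen_aln + k },
             "D" = { ref <- ref + k; del <- del + k },
             "I" = { qlen_aln <- qlen_aln + k; ins <- ins + k },
             "S" = , "H" = { qlen_clip <- qlen_clip + k },
             "N" = { exs[[length(exs) + 1L]] <- c(ex_start, ref)
                     ref <- ref + k; ex_start <- ref },
             "P" = NULL)
    }
    exs[[length(exs) + 1L]] <- c(ex_start, ref)
    nm <- suppressWarnings(as.integer(sub("^NM:i:", "", grep("^NM:i:", f, value = TRUE)[1L])))
    identity <- if (!is.na(nm)) max(0, (qlen_aln - nm) / qlen_aln) else NA_real_
    coverage <- qlen_aln / (qlen_aln + qlen_clip)
    id <- f[1L]
    em <- do.call(rbind, exs)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      transcript_id = id, chrom = f[3L], start = em[, 1L], end = em[, 2L],
      strand = strand, stringsAsFactors = FALSE)
    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      transcript_id = id, gene_id = NA_character_,
      identity = identity, coverage = coverage, stringsAsFactors = FALSE)
  }
  if (!length(exon_rows))
    return(list(models = transcript_set(
      data.frame(transcript_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character())),
      n_unmapped = n_unmapped))
  list(models = transcript_set(do.call(rbind, exon_rows), do.call(rbind, tx_rows)),
       n_unmapped = n_unmapped)
}
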