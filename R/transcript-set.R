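#' Transcript models as exon chains
#'
#' A `transcript_set` holds one or more transcript models, each an ordered
#' chain of exons on a single chromosome and strand. It is the universal
#' currency of the pipeline: aligned long reads, collapsed isoforms and
#' reference transcripts are all represented this way.
#'
#' All coordinates are 0-based half-open internally; GTF/SJ dialect
#' conversion happens at the I/O boundary only.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` (one row per exon, 0-based half-open).
#' @param transcripts optional data.frame with one row per transcript and at
#'   least columns `transcript_id`, `gene_id`. Extra columns (e.g. alignment
#'   `identity` and `coverage`) are carried through untouched. When absent, a
#'   minimal table is derived with `gene_id = NA`.
#' @param validate check structural invariants (sorted non-overlapping exons,
#'   single chrom/strand per transcript, gaps >= 1 nt). Default TRUE.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(exons, transcripts = NULL, validate = TRUE) {
  stopifnot(is.data.frame(exons))
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exons is missing columns: ", paste(miss, collapse = ", "))
  exons <- exons[order(exons$transcript_id, exons$start), need, drop = FALSE]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL

  if (is.null(transcripts)) {
    ids <- unique(exons$transcript_id)
    transcripts <- data.frame(transcript_id = ids, gene_id = NA_character_,
                              stringsAsFactors = FALSE)
  }
  transcripts$transcript_id <- as.character(transcripts$transcript_id)
  if (is.null(transcripts$gene_id)) transcripts$gene_id <- NA_character_
  rownames(transcripts) <- NULL

  obj <- structure(list(exons = exons, transcripts = transcripts),
                   class = "transcript_set")
  if (validate) validate_transcript_set(obj)
  obj
}

validate_transcript_set <- function(x) {
  ex <- x$exons
  if (any(ex$start < 0L) || any(ex$end <= ex$start))
    stop("invalid exon interval: require 0 <= start < end")
  if (!all(ex$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (id in names(sp)) {
    rows <- ex[sp[[id]], , drop = FALSE]
    if (length(unique(rows$chrom)) != 1L || length(unique(rows$strand)) != 1L)
      stop("transcript '", id, "' has exons on mixed chromosomes or strands")
    if (nrow(rows) > 1L) {
      gaps <- rows$start[-1L] - rows$end[-nrow(rows)]
      if (any(gaps < 1L))
        stop("transcript '", id, "' has overlapping or abutting exons (intron gap < 1 nt)")
    }
  }
  extra <- setdiff(unique(ex$transcript_id), x$transcripts$transcript_id)
  if (length(extra)) stop("exons reference transcripts absent from the transcript table")
  invisible(x)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d exons, %d gene(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(stats::na.omit(x$transcripts$gene_id)))))
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$transcripts)

#' Per-transcript summary table
#'
#' One row per transcript: chrom, strand, genomic span, exon count and
#' spliced (exonic) length.
#' @param x a `transcript_set`
#' @return data.frame keyed by `transcript_id`
#' @export
tx_table <- function(x) {
  ex <- x$exons
  agg <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(r) {
    data.frame(transcript_id = r$transcript_id[1L], chrom = r$chrom[1L],
               strand = r$strand[1L], start = min(r$start), end = max(r$end),
               n_exons = nrow(r), exonic_len = sum(r$end - r$start),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  out <- merge(x$transcripts, agg, by = "transcript_id", sort = FALSE)
  out[match(x$transcripts$transcript_id, out$transcript_id), , drop = FALSE]
}

#' Introns of every transcript
#'
#' @param x a `transcript_set`
#' @return data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open intron coordinates), ordered 5'->3'
#'   in genomic orientation. Mono-exon transcripts contribute no rows.
#' @export
introns_table <- function(x) {
  ex <- x$exons
  res <- lapply(split(ex, ex$transcript_id), function(r) {
    if (nrow(r) < 2L) return(NULL)
    data.frame(transcript_id = r$transcript_id[1L], chrom = r$chrom[1L],
               strand = r$strand[1L],
               start = r$end[-nrow(r)], end = r$start[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intron-chain keys
#'
#' A string key identifying each transcript's ordered intron chain on its
#' chrom/strand; mono-exon transcripts get key `NA`. Two multi-exon
#' transcripts are structurally identical iff their keys are equal.
#' @param x a `transcript_set`
#' @return named character vector, names = transcript ids
#' @export
chain_keys <- function(x) {
  ex <- x$exons
  vapply(split(ex, ex$transcript_id), function(r) {
    if (nrow(r) < 2L) return(NA_character_)
    paste0(r$chrom[1L], r$strand[1L], ":",
           paste(r$end[-nrow(r)], r$start[-1L], sep = "-", collapse = ";"))
  }, character(1L))
}

#' Subset a transcript_set by transcript id
#' @param x a `transcript_set`
#' @param ids transcript ids to keep
#' @return a `transcript_set`
#' @export
subset_transcripts <- function(x, ids) {
  transcript_set(x$exons[x$exons$transcript_id %in% ids, , drop = FALSE],
                 x$transcripts[x$transcripts$transcript_id %in% ids, , drop = FALSE],
                 validate = FALSE)
}

#' Exons of a single transcript
#' @param x a `transcript_set`
#' @param id one transcript id
#' @return data.frame of its exons, sorted by start
#' @export
exons_of <- function(x, id) {
  r <- x$exons[x$exons$transcript_id == id, , drop = FALSE]
  if (!nrow(r)) stop("unknown transcript id: ", id)
  r
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in transcript (5'->3') orientation; on the
#' minus strand the genomic concatenation is reverse-complemented.
#' @param x a `transcript_set`
#' @param genome a genome as returned by [read_genome()]
#' @param ids transcript ids (default: all)
#' @return named character vector of sequences
#' @export
spliced_sequence <- function(x, genome, ids = x$transcripts$transcript_id) {
  vapply(ids, function(id) {
    r <- exons_of(x, id)
    s <- paste0(vapply(seq_len(nrow(r)), function(i)
      fetch_sequence(genome, r$chrom[i], r$start[i], r$end[i], "+"),
      character(1L)), collapse = "")
    if (r$strand[1L] == "-") s <- revcomp(s)
    s
  }, character(1L))
}
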