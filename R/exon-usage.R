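#' Flatten gene models into disjoint exon counting bins
#'
#' Projects all exon boundaries of each gene onto the genomic axis and emits
#' the maximal disjoint fragments covered by at least one exon, merging
#' adjacent fragments covered by the same transcript set. Bins whose
#' interval overlaps another gene's exons are flagged ambiguous (excluded
#' from testing downstream).
#'
#' @param models a `transcript_set` with gene ids
#' @return data.frame of bins: gene_id, bin_id (gene-scoped ordinal), chrom,
#'   strand, start, end, source_transcripts (comma-separated), ambiguous
#' @export
flatten_gene_models <- function(models) {
  tt <- tx_table(models)
  if (any(is.na(tt$gene_id))) stop("flatten_gene_models requires gene_id")
  ex <- models$exons
  ex$gene_id <- tt$gene_id[match(ex$transcript_id, tt$transcript_id)]
  out <- list()
  for (g in split(ex, ex$gene_id)) {
    bounds <- sort(unique(c(g$start, g$end)))
    frag <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
    cover <- lapply(seq_len(nrow(frag)), function(i)
      sort(unique(g$transcript_id[g$start <= frag$start[i] & frag$end[i] <= g$end])))
    keep <- lengths(cover) > 0L
    frag <- frag[keep, , drop = FALSE]; cover <- cover[keep]
    if (!nrow(frag)) next
    # merge adjacent fragments with identical covering transcript sets
    sig <- vapply(cover, paste, character(1L), collapse = ",")
    merged <- list(); cur <- 1L
    for (i in seq_len(nrow(frag))[-1L]) {
      if (frag$start[i] == frag$end[cur] && sig[i] == sig[cur]) {
        frag$end[cur] <- frag$end[i]
      } else {
        merged[[length(merged) + 1L]] <- c(cur)
        cur <- i
      }
    }
    merged[[length(merged) + 1L]] <- c(cur)
    idx <- unlist(merged)
    bins <- data.frame(gene_id = g$gene_id[1L],
                       bin_id = sprintf("%s:%03d", g$gene_id[1L], seq_along(idx)),
                       chrom = g$chrom[1L], strand = g$strand[1L],
                       start = frag$start[idx], end = frag$end[idx],
                       source_transcripts = sig[idx], stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- bins
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  # ambiguity: bin overlaps a different gene's exons
  gr_bins <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  gr_ex <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_ex, ignore.strand = TRUE)
  amb <- tapply(ex$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits),
                function(gs) length(unique(gs)) > 1L)
  bins$ambiguous <- FALSE
  bins$ambiguous[as.integer(names(amb))] <- unname(amb)
  bins
}

#' Count reads over exon counting bins
#'
#' A read (a chain of aligned intervals) increments every bin that any of its
#' segments overlaps by at least `min_overlap` nt. Counting is unstranded by
#' default. Reads on chromosomes absent from the bin set are tallied as
#' unassigned.
#'
#' @param read_intervals named list (one element per sample) of data.frames
#'   with columns read_id, chrom, start, end (0-based half-open; several rows
#'   per spliced read) and optionally strand
#' @param bins bin table from [flatten_gene_models()]
#' @param min_overlap minimum overlap in nt (default 1)
#' @param stranded require matching strand (default FALSE)
#' @return list: `counts` (integer matrix bins x samples, rownames bin_id),
#'   `n_unassigned` (per sample)
#' @export
count_reads_in_bins <- function(read_intervals, bins, min_overlap = 1L,
                                stranded = FALSE) {
  samples <- names(read_intervals)
  counts <- matrix(0L, nrow = nrow(bins), ncol = length(samples),
                   dimnames = list(bins$bin_id, samples))
  n_unassigned <- stats::setNames(integer(length(samples)), samples)
  gr_bins <- GenomicRanges::GRanges(bins$chrom,
    IRanges::IRanges(bins$start + 1L, bins$end),
    strand = if (stranded) bins$strand else "*")
  for (s in samples) {
    rd <- read_intervals[[s]]
    if (!nrow(rd)) next
    known_chrom <- rd$chrom %in% bins$chrom
    if (any(!known_chrom)) {
      n_unassigned[s] <- length(unique(rd$read_id[!known_chrom]))
      rd <- rd[known_chrom, , drop = FALSE]
      if (!nrow(rd)) next
    }
    gr_rd <- GenomicRanges::GRanges(rd$chrom,
      IRanges::IRanges(rd$start + 1L, rd$end),
      strand = if (stranded && !is.null(rd$strand)) rd$strand else "*")
    hits <- GenomicRanges::findOverlaps(gr_rd, gr_bins,
                                        minoverlap = min_overlap,
                                        ignore.strand = !stranded)
    if (!length(hits)) next
    pairs <- unique(data.frame(read = rd$read_id[S4Vectors::queryHits(hits)],
                               bin = S4Vectors::subjectHits(hits)))
    tab <- table(pairs$bin)
    counts[as.integer(names(tab)), s] <- as.integer(tab)
  }
  list(counts = counts, n_unassigned = n_unassigned)
}

#' Differential exon usage between two conditions
#'
#' Counts are pooled within condition; for each bin a 2x2 table (bin count vs
#' count on the gene's other bins; condition A vs condition B) is tested with
#' Fisher's exact conditional test. The log2 fold-change is the log-ratio of
#' usage ratios (bin / rest-of-gene, pseudocount 0.5), condition B over
#' condition A. P-values are BH-adjusted across all tested bins. Bins with
#' fewer than `min_count` total reads, ambiguous bins, and bins of
#' single-bin genes are reported untested.
#'
#' @param counts integer matrix bins x samples (rownames = bin_id, matching
#'   `bins$bin_id`)
#' @param bins bin table from [flatten_gene_models()]
#' @param condition character/factor of length ncol(counts) with exactly two
#'   levels
#' @param min_count low-count gate (default 10)
#' @return data.frame sorted by adj_p_value: gene_id, bin_id, count_A,
#'   count_B, usage_ratio_A, usage_ratio_B, log2_fc, p_value, adj_p_value,
#'   tested
#' @export
differential_usage <- function(counts, bins, condition, min_count = 10L) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  if (length(condition) != ncol(counts)) stop("condition length != number of samples")
  lvl <- levels(condition)
  a <- rowSums(counts[, condition == lvl[1L], drop = FALSE])
  b <- rowSums(counts[, condition == lvl[2L], drop = FALSE])
  ord <- match(bins$bin_id, rownames(counts))
  if (any(is.na(ord))) stop("counts rownames do not cover the bin table")
  a <- a[ord]; b <- b[ord]
  gene_a <- tapply(a, bins$gene_id, sum)[bins$gene_id]
  gene_b <- tapply(b, bins$gene_id, sum)[bins$gene_id]
  bins_per_gene <- table(bins$gene_id)[bins$gene_id]
  rest_a <- gene_a - a; rest_b <- gene_b - b

  tested <- !bins$ambiguous & (a + b) >= min_count & bins_per_gene > 1L
  p <- rep(NA_real_, nrow(bins))
  for (i in which(tested))
    p[i] <- stats::fisher.test(matrix(c(a[i], rest_a[i], b[i], rest_b[i]), nrow = 2L))$p.value
  ratio_a <- (a + 0.5) / (rest_a + 0.5)
  ratio_b <- (b + 0.5) / (rest_b + 0.5)
  lfc <- log2(ratio_b / ratio_a)
  adj <- rep(NA_real_, nrow(bins))
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(gene_id = bins$gene_id, bin_id = bins$bin_id,
                    count_A = unname(a), count_B = unname(b),
                    usage_ratio_A = unname(a / pmax(rest_a, 1)),
                    usage_ratio_B = unname(b / pmax(rest_b, 1)),
                    log2_fc = unname(lfc), p_value = unname(p),
                    adj_p_value = unname(adj), tested = unname(tested),
                    stringsAsFactors = FALSE)
  out[order(out$adj_p_value, out$p_value), , drop = FALSE]
}
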