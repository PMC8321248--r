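#' Index a reference annotation for classification queries
#'
#' Precomputes everything the structural classifier needs: per-transcript
#' intron chains, the annotated junction set, annotated donor/acceptor site
#' sets (strand-aware), per-gene extents and `GRanges` indices over gene
#' bodies and exons.
#'
#' @param ref a `transcript_set` of reference transcripts (gene ids required)
#' @return an object of class `annotation_index`
#' @export
annotation_index <- function(ref) {
  stopifnot(inherits(ref, "transcript_set"))
  if (any(is.na(ref$transcripts$gene_id)))
    stop("reference transcripts must carry gene_id")
  tt <- tx_table(ref)
  intr <- introns_table(ref)
  intr$gene_id <- tt$gene_id[match(intr$transcript_id, tt$transcript_id)]

  jkey <- unique(paste0(intr$chrom, intr$strand, ":", intr$start, "-", intr$end))
  donors <- ifelse(intr$strand == "+", intr$start, intr$end)
  acceptors <- ifelse(intr$strand == "+", intr$end, intr$start)
  donor_key <- unique(paste0(intr$chrom, intr$strand, ":", donors))
  acceptor_key <- unique(paste0(intr$chrom, intr$strand, ":", acceptors))

  genes <- do.call(rbind, lapply(split(tt, tt$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L], strand = g$strand[1L],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  gr_genes <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end), strand = genes$strand)
  names(gr_genes) <- genes$gene_id
  ex <- ref$exons
  ex$gene_id <- tt$gene_id[match(ex$transcript_id, tt$transcript_id)]
  gr_exons <- GenomicRanges::GRanges(ex$chrom,
    IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand)
  S4Vectors::mcols(gr_exons)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr_exons)$transcript_id <- ex$transcript_id

  structure(list(
    ref = ref, tx = tt, introns = intr,
    chains = chain_keys(ref),
    junction_keys = jkey,
    donor_keys = donor_key,
    acceptor_keys = acceptor_key,
    genes = genes, gr_genes = gr_genes, gr_exons = gr_exons
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d genes, %d transcripts, %d junctions\n",
              nrow(x$genes), nrow(x$tx), length(x$junction_keys)))
  invisible(x)
}

#' Is a junction annotated?
#' @param ann an `annotation_index`
#' @param chrom,strand,start,end junction coordinates (0-based half-open),
#'   vectorized
#' @return logical vector
#' @export
junction_known <- function(ann, chrom, strand, start, end) {
  paste0(chrom, strand, ":", start, "-", end) %in% ann$junction_keys
}

# Genes whose body overlaps [start,end) on chrom; strand "+"/"-" filters to
# that strand, NULL returns both.
overlapping_genes <- function(ann, chrom, start, end, strand = NULL) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, ann$gr_genes, ignore.strand = TRUE)
  g <- ann$genes[S4Vectors::subjectHits(hits), , drop = FALSE]
  if (!is.null(strand)) g <- g[g$strand == strand, , drop = FALSE]
  g
}

# Total exonic overlap (nt) between an exon data.frame and a gene's exons.
exonic_overlap_with_gene <- function(ann, exons, gene_id) {
  ref_ex <- ann$ref$exons
  gid <- ann$tx$gene_id[match(ref_ex$transcript_id, ann$tx$transcript_id)]
  ref_ex <- ref_ex[gid == gene_id, , drop = FALSE]
  if (!nrow(ref_ex)) return(0L)
  ir_a <- IRanges::reduce(IRanges::IRanges(exons$start + 1L, exons$end))
  ir_b <- IRanges::reduce(IRanges::IRanges(ref_ex$start + 1L, ref_ex$end))
  sum(IRanges::width(IRanges::intersect(ir_a, ir_b)))
}
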