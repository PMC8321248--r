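CATEGORIES <- c("FSM", "ISM", "FUSION", "NIC", "NNC",
                "GENIC_INTRON", "GENIC_GENOMIC", "ANTISENSE", "INTERGENIC")

#' Type the splice junctions of transcript models
#'
#' Reads donor/acceptor dinucleotides strand-aware from the genome (so GT-AG
#' is canonical on both strands), and looks each intron up in the annotated
#' junction set. Mono-exon models contribute no rows.
#'
#' @param models a `transcript_set`
#' @param genome genome from [read_genome()]
#' @param ann an `annotation_index` (or NULL: `known` reported as NA)
#' @return data.frame, one row per intron: transcript_id, chrom, strand,
#'   start, end, donor, acceptor, canonical, known
#' @export
classify_junctions <- function(models, genome, ann = NULL) {
  intr <- introns_table(models)
  if (!nrow(intr)) {
    return(data.frame(transcript_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      donor = character(), acceptor = character(),
                      canonical = logical(), known = logical(),
                      stringsAsFactors = FALSE))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(intr$end > chrom_len[intr$chrom]) || any(intr$start < 0L)) {
    bad <- which(intr$end > chrom_len[intr$chrom] | intr$start < 0L)[1L]
    stop(sprintf("intron extends past chromosome end: %s:%d-%d",
                 intr$chrom[bad], intr$start[bad], intr$end[bad]))
  }
  donor <- character(nrow(intr)); acceptor <- character(nrow(intr))
  for (i in seq_len(nrow(intr))) {
    if (intr$strand[i] == "+") {
      donor[i] <- fetch_sequence(genome, intr$chrom[i], intr$start[i], intr$start[i] + 2L)
      acceptor[i] <- fetch_sequence(genome, intr$chrom[i], intr$end[i] - 2L, intr$end[i])
    } else {
      donor[i] <- fetch_sequence(genome, intr$chrom[i], intr$end[i] - 2L, intr$end[i], "-")
      acceptor[i] <- fetch_sequence(genome, intr$chrom[i], intr$start[i], intr$start[i] + 2L, "-")
    }
  }
  canonical <- paste(donor, acceptor) %in% c("GT AG", "GC AG", "AT AC")
  known <- if (is.null(ann)) NA else
    junction_known(ann, intr$chrom, intr$strand, intr$start, intr$end)
  data.frame(intr[, c("transcript_id", "chrom", "strand", "start", "end")],
             donor = donor, acceptor = acceptor,
             canonical = canonical, known = known, stringsAsFactors = FALSE)
}

# Wrapped ";s-e;...;" token strings for contiguous sub-chain search.
wrapped_chain <- function(chains) {
  ifelse(is.na(chains), NA_character_,
         paste0(";", sub("^[^:]*:", "", chains), ";"))
}

#' Signed distances of model ends to a matched reference's TSS/TTS
#'
#' Both distances are in transcript orientation: positive means the model end
#' lies downstream of the reference end, negative upstream.
#'
#' @param model_row one row of [tx_table()] for the model
#' @param ref_row one row of [tx_table()] for the matched reference
#' @return named numeric vector c(dist5, dist3)
#' @export
terminal_distances <- function(model_row, ref_row) {
  if (model_row$strand != ref_row$strand || model_row$chrom != ref_row$chrom)
    stop("terminal_distances: model and reference on different chrom/strand")
  if (model_row$strand == "+")
    c(dist5 = model_row$start - ref_row$start, dist3 = model_row$end - ref_row$end)
  else
    c(dist5 = ref_row$end - model_row$end, dist3 = ref_row$start - model_row$start)
}

# classify one model; internals shared by classify_transcripts
classify_one <- function(r, trow, ann, mono_fsm_tol = 100L) {
  chrom <- trow$chrom; strand <- trow$strand
  n_ex <- nrow(r)
  ref_tx <- ann$tx
  same_cs <- ref_tx$chrom == chrom & ref_tx$strand == strand

  res <- list(category = "INTERGENIC", genes = character(),
              matched = NA_character_, dist5 = NA_real_, dist3 = NA_real_)
  best_match <- function(cand_ids) {
    # among candidate reference transcripts, minimal total terminal offset
    d <- vapply(cand_ids, function(id) {
      td <- terminal_distances(trow, ref_tx[ref_tx$transcript_id == id, ])
      sum(abs(td))
    }, numeric(1L))
    cand_ids[order(d, cand_ids)][1L]
  }
  finish_match <- function(category, id) {
    rr <- ref_tx[ref_tx$transcript_id == id, ]
    td <- terminal_distances(trow, rr)
    res$category <<- category; res$matched <<- id
    res$genes <<- rr$gene_id; res$dist5 <<- td[["dist5"]]; res$dist3 <<- td[["dist3"]]
  }

  if (n_ex > 1L) {
    tok <- paste(r$end[-n_ex], r$start[-1L], sep = "-")
    mkey <- paste0(chrom, strand, ":", paste(tok, collapse = ";"))
    wrapped <- paste0(";", paste(tok, collapse = ";"), ";")
    cand <- ref_tx$transcript_id[same_cs]
    ref_chains <- ann$chains[cand]

    hit_fsm <- cand[!is.na(ref_chains) & ref_chains == mkey]
    if (length(hit_fsm)) { finish_match("FSM", best_match(hit_fsm)); return(res) }

    wref <- wrapped_chain(ref_chains)
    hit_ism <- cand[!is.na(wref) & vapply(wref, function(w) grepl(wrapped, w, fixed = TRUE), logical(1L))]
    if (length(hit_ism)) { finish_match("ISM", best_match(hit_ism)); return(res) }

    # junction-sharing genes (for fusion and gene association)
    jkey <- paste0(chrom, strand, ":", tok)
    ri <- ann$introns[ann$introns$chrom == chrom & ann$introns$strand == strand, , drop = FALSE]
    rikey <- paste0(ri$chrom, ri$strand, ":", ri$start, "-", ri$end)
    shared_genes <- unique(ri$gene_id[rikey %in% jkey])
    if (length(shared_genes) >= 2L) {
      g <- ann$genes[match(shared_genes, ann$genes$gene_id), ]
      sep_pair <- FALSE
      for (a in seq_len(nrow(g) - 1L)) for (b in (a + 1L):nrow(g))
        if (g$end[a] <= g$start[b] || g$end[b] <= g$start[a]) sep_pair <- TRUE
      if (sep_pair) {
        res$category <- "FUSION"; res$genes <- sort(shared_genes); return(res)
      }
    }

    donors <- if (strand == "+") r$end[-n_ex] else r$start[-1L]
    acceptors <- if (strand == "+") r$start[-1L] else r$end[-n_ex]
    site_known <- c(paste0(chrom, strand, ":", donors) %in% ann$donor_keys,
                    paste0(chrom, strand, ":", acceptors) %in% ann$acceptor_keys)

    assoc <- associated_gene(ann, r, chrom, strand, jkey)
    exonic_ov <- exonic_overlap_any(ann, r, chrom, strand)
    if (all(site_known)) {
      res$category <- "NIC"; res$genes <- assoc; return(res)
    }
    if (exonic_ov) {
      res$category <- "NNC"; res$genes <- assoc; return(res)
    }
  } else {
    # mono-exon: containment rules against reference exons
    rex <- ann$ref$exons
    rex <- rex[rex$chrom == chrom & rex$strand == strand, , drop = FALSE]
    contain <- rex[rex$start <= r$start & r$end <= rex$end, , drop = FALSE]
    if (nrow(contain)) {
      nref_exons <- ann$tx$n_exons[match(contain$transcript_id, ann$tx$transcript_id)]
      mono_ref <- contain[nref_exons == 1L &
                            abs(contain$start - r$start) <= mono_fsm_tol &
                            abs(contain$end - r$end) <= mono_fsm_tol, , drop = FALSE]
      if (nrow(mono_ref)) { finish_match("FSM", best_match(unique(mono_ref$transcript_id))); return(res) }
      finish_match("ISM", best_match(unique(contain$transcript_id))); return(res)
    }
  }

  # genic-intron / genic-genomic / antisense / intergenic
  ri <- ann$introns[ann$introns$chrom == chrom & ann$introns$strand == strand, , drop = FALSE]
  inside <- ri[ri$start <= min(r$start) & max(r$end) <= ri$end, , drop = FALSE]
  if (nrow(inside)) {
    res$category <- "GENIC_INTRON"; res$genes <- unique(inside$gene_id)[1L]; return(res)
  }
  g_same <- overlapping_genes(ann, chrom, min(r$start), max(r$end), strand)
  if (nrow(g_same)) {
    ov <- vapply(g_same$gene_id, function(g) exonic_overlap_with_gene(ann, r, g), numeric(1L))
    res$category <- "GENIC_GENOMIC"
    res$genes <- g_same$gene_id[order(-ov, g_same$gene_id)][1L]
    return(res)
  }
  g_anti <- overlapping_genes(ann, chrom, min(r$start), max(r$end),
                              if (strand == "+") "-" else "+")
  if (nrow(g_anti)) {
    res$category <- "ANTISENSE"; res$genes <- g_anti$gene_id; return(res)
  }
  res
}

# same-strand gene with the greatest shared-junction count, ties by exonic
# overlap length, then lexicographic
associated_gene <- function(ann, r, chrom, strand, jkey) {
  ri <- ann$introns[ann$introns$chrom == chrom & ann$introns$strand == strand, , drop = FALSE]
  rikey <- paste0(ri$chrom, ri$strand, ":", ri$start, "-", ri$end)
  gk <- unique(data.frame(g = ri$gene_id, k = rikey, stringsAsFactors = FALSE))
  shared <- table(gk$g[gk$k %in% jkey])
  g_ov <- overlapping_genes(ann, chrom, min(r$start), max(r$end), strand)
  cand <- union(names(shared), g_ov$gene_id)
  if (!length(cand)) return(character())
  nj <- ifelse(cand %in% names(shared), as.integer(shared[cand]), 0L)
  ov <- vapply(cand, function(g) exonic_overlap_with_gene(ann, r, g), numeric(1L))
  cand[order(-nj, -ov, cand)][1L]
}

exonic_overlap_any <- function(ann, r, chrom, strand) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(r$start + 1L, r$end), strand = strand)
  length(GenomicRanges::findOverlaps(q, ann$gr_exons, ignore.strand = FALSE)) > 0L
}

#' Structural classification of isoforms against a reference annotation
#'
#' Assigns each model exactly one of nine categories by a fixed precedence:
#' FSM (intron chain identical to a reference transcript), ISM (chain a
#' contiguous sub-chain of one), FUSION (junctions hit two non-overlapping
#' annotated loci), NIC (all splice sites annotated, chain novel), NNC (at
#' least one unannotated site, exonic overlap with a same-strand gene),
#' GENIC_INTRON (model inside one annotated intron), GENIC_GENOMIC (partial
#' same-strand gene overlap), ANTISENSE (only opposite-strand gene overlap),
#' INTERGENIC (no gene overlap). Mono-exon models match FSM when contained in
#' a mono-exon reference exon with both ends within `mono_fsm_tol` nt, ISM
#' when contained in any reference exon.
#'
#' @param models a `transcript_set`
#' @param ann an `annotation_index`
#' @param genome optional genome; when given, junction typing columns
#'   (n_canonical, n_known) are filled from [classify_junctions()]
#' @param mono_fsm_tol end tolerance for mono-exon FSM (default 100)
#' @return data.frame, one row per model: transcript_id, category,
#'   associated_genes (comma-separated), matched_transcript_id, dist5, dist3,
#'   n_junctions, n_known, n_canonical
#' @export
classify_transcripts <- function(models, ann, genome = NULL, mono_fsm_tol = 100L) {
  tt <- tx_table(models)
  jinfo <- if (!is.null(genome)) classify_junctions(models, genome, ann) else NULL
  rows <- lapply(seq_len(nrow(tt)), function(i) {
    id <- tt$transcript_id[i]
    r <- exons_of(models, id)
    cl <- classify_one(r, tt[i, , drop = FALSE], ann, mono_fsm_tol)
    nj <- nrow(r) - 1L
    nk <- nc <- NA_integer_
    if (!is.null(jinfo)) {
      j <- jinfo[jinfo$transcript_id == id, , drop = FALSE]
      nk <- sum(j$known); nc <- sum(j$canonical)
    }
    data.frame(transcript_id = id, category = cl$category,
               associated_genes = paste(cl$genes, collapse = ","),
               matched_transcript_id = cl$matched,
               dist5 = cl$dist5, dist3 = cl$dist3,
               n_junctions = nj, n_known = nk, n_canonical = nc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize structural categories and known/novel genes
#'
#' @param calls output of [classify_transcripts()]
#' @param models the classified `transcript_set`
#' @param ann the `annotation_index`
#' @return list: `categories` (data.frame category/count/fraction over the
#'   nine categories present), `n_known_genes`, `n_novel_genes` (clusters of
#'   non-FSM/ISM models without same-strand annotated overlap, merged by
#'   exonic overlap)
#' @export
summarize_categories <- function(calls, models, ann) {
  if (!nrow(calls))
    return(list(categories = data.frame(category = character(), count = integer(),
                                        fraction = numeric(), stringsAsFactors = FALSE),
                n_known_genes = 0L, n_novel_genes = 0L))
  cnt <- table(factor(calls$category, levels = CATEGORIES))
  cnt <- cnt[cnt > 0L]
  categories <- data.frame(category = names(cnt), count = as.integer(cnt),
                           fraction = as.numeric(cnt) / nrow(calls),
                           stringsAsFactors = FALSE)
  known <- unique(unlist(strsplit(calls$associated_genes[
    calls$category %in% c("FSM", "ISM", "FUSION", "NIC", "NNC",
                          "GENIC_INTRON", "GENIC_GENOMIC")], ",")))
  known <- known[known != ""]

  # novel genes: non-FSM/ISM models with no same-strand annotated overlap
  tt <- tx_table(models)
  nf <- calls$transcript_id[!calls$category %in% c("FSM", "ISM")]
  novel_ids <- nf[vapply(nf, function(id) {
    m <- tt[tt$transcript_id == id, ]
    nrow(overlapping_genes(ann, m$chrom, m$start, m$end, m$strand)) == 0L
  }, logical(1L))]
  n_novel <- 0L
  if (length(novel_ids)) {
    ex <- models$exons[models$exons$transcript_id %in% novel_ids, , drop = FALSE]
    gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
                                 strand = ex$strand)
    red <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
    comp <- GenomicRanges::findOverlaps(gr, red)
    # single-linkage: transcripts sharing a reduced exonic block are one gene
    memb <- tapply(S4Vectors::subjectHits(comp), ex$transcript_id[S4Vectors::queryHits(comp)],
                   function(v) min(v))
    # merge transitively: transcripts are linked through shared blocks
    blocks <- tapply(S4Vectors::subjectHits(comp), ex$transcript_id[S4Vectors::queryHits(comp)],
                     unique)
    ids <- names(blocks)
    parent <- stats::setNames(seq_along(ids), ids)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    block_owner <- list()
    for (i in seq_along(ids)) {
      for (b in blocks[[i]]) {
        key <- as.character(b)
        if (is.null(block_owner[[key]])) block_owner[[key]] <- i
        else { ra <- find(block_owner[[key]]); rb <- find(i); if (ra != rb) parent[rb] <- ra }
      }
    }
    n_novel <- length(unique(vapply(seq_along(ids), find, integer(1L))))
  }
  list(categories = categories, n_known_genes = length(known), n_novel_genes = n_novel)
}
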