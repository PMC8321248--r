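EVENT_KINDS <- c("IR", "ES", "ME", "MX", "A3SS", "A5SS")

# Pairwise structural comparison of two exon chains (same chrom/strand).
# Returns zero or more event rows. a_id/b_id are the isoform ids; ra/rb their
# exon data.frames sorted by start.
compare_pair <- function(a_id, b_id, ra, rb, gene_id) {
  chrom <- ra$chrom[1L]; strand <- ra$strand[1L]
  out <- list()
  emit <- function(kind, vs, ve, inc, exc, extra = "") {
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, gene_id = gene_id, chrom = chrom, strand = strand,
      var_start = vs, var_end = ve, inclusion = inc, exclusion = exc,
      detail = extra, stringsAsFactors = FALSE)
  }
  introns <- function(r) {
    n <- nrow(r)
    if (n < 2L) return(data.frame(start = integer(), end = integer()))
    data.frame(start = r$end[-n], end = r$start[-1L])
  }
  ia <- introns(ra); ib <- introns(rb)

  # --- intron retention: an intron of one isoform interior to an exon of the
  # other; exclusion evidence = the isoform that splices
  ir_scan <- function(spliced, retained, s_id, r_id) {
    for (j in seq_len(nrow(spliced))) {
      s <- spliced$start[j]; e <- spliced$end[j]
      if (any(retained$start < s & e < retained$end))
        emit("IR", s, e, r_id, s_id)
    }
  }
  ir_scan(ia, rb, a_id, b_id)
  ir_scan(ib, ra, b_id, a_id)

  # --- exon skipping (1 exon) / multiple exon skips (>= 2 consecutive):
  # an intron of the skipping isoform whose boundaries are splice sites of
  # the other, with >= 1 exon of the other strictly inside
  es_scan <- function(skip_intr, other, skip_id, other_id) {
    for (j in seq_len(nrow(skip_intr))) {
      s <- skip_intr$start[j]; e <- skip_intr$end[j]
      if (!any(other$end == s) || !any(other$start == e)) next
      inside <- other[other$start > s & other$end < e, , drop = FALSE]
      if (!nrow(inside)) next
      kind <- if (nrow(inside) == 1L) "ES" else "ME"
      emit(kind, min(inside$start), max(inside$end), other_id, skip_id,
           paste(inside$start, inside$end, sep = "-", collapse = ","))
    }
  }
  es_scan(ia, rb, a_id, b_id)
  es_scan(ib, ra, b_id, a_id)

  # --- mutually exclusive exons: shared donor-side and acceptor-side
  # boundaries with disjoint non-empty internal exon sets in between
  shared_L <- intersect(ra$end[-nrow(ra)], rb$end[-nrow(rb)])
  shared_R <- intersect(ra$start[-1L], rb$start[-1L])
  for (d in shared_L) for (acc in shared_R) {
    if (acc <= d) next
    ea <- ra[ra$start > d & ra$end < acc, , drop = FALSE]
    eb <- rb[rb$start > d & rb$end < acc, , drop = FALSE]
    if (!nrow(ea) || !nrow(eb)) next
    # maximality: no shared boundary strictly inside (d, acc)
    inner_shared <- c(intersect(ea$start, eb$start), intersect(ea$end, eb$end))
    if (length(inner_shared)) next
    ov <- IRanges::intersect(IRanges::IRanges(ea$start + 1L, ea$end),
                             IRanges::IRanges(eb$start + 1L, eb$end))
    if (sum(IRanges::width(ov)) > 0L) next
    ids <- sort(c(a_id, b_id))
    coords <- paste(sort(c(paste(ea$start, ea$end, sep = "-"),
                           paste(eb$start, eb$end, sep = "-"))), collapse = ",")
    emit("MX", min(c(ea$start, eb$start)), max(c(ea$end, eb$end)),
         ids[1L], ids[2L], coords)
  }

  # --- alternative 5'/3' splice sites: intron pair sharing exactly one
  # boundary; named in transcript orientation (donor = 5' splice site)
  for (j in seq_len(nrow(ia))) for (l in seq_len(nrow(ib))) {
    s1 <- ia$start[j]; e1 <- ia$end[j]; s2 <- ib$start[l]; e2 <- ib$end[l]
    if (e1 == e2 && s1 != s2) {
      # differing intron start = donor side on +, acceptor side on -
      kind <- if (strand == "+") "A5SS" else "A3SS"
      longer <- if (s1 < s2) a_id else b_id   # larger intron = exclusion of the region
      shorter <- if (s1 < s2) b_id else a_id
      # the isoform with the later intron start must be exonic across the gap
      rsh <- if (s1 < s2) rb else ra
      if (!any(rsh$start <= min(s1, s2) & rsh$end >= max(s1, s2))) next
      emit(kind, min(s1, s2), max(s1, s2), shorter, longer, paste0("J", e1))
    } else if (s1 == s2 && e1 != e2) {
      kind <- if (strand == "+") "A3SS" else "A5SS"
      longer <- if (e1 > e2) a_id else b_id
      shorter <- if (e1 > e2) b_id else a_id
      rsh <- if (e1 > e2) rb else ra
      if (!any(rsh$start <= min(e1, e2) & rsh$end >= max(e1, e2))) next
      emit(kind, min(e1, e2), max(e1, e2), shorter, longer, paste0("J", s1))
    }
  }

  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Enumerate alternative-splicing events at each locus
#'
#' Every isoform pair of a gene is compared structurally; maximal variable
#' regions bounded by shared splice sites are classified as intron retention
#' (IR), exon skipping (ES), multiple exon skips (ME), mutually exclusive
#' exons (MX) or alternative 5'/3' splice sites (A5SS/A3SS, named in
#' transcript orientation). Identical events evidenced by different pairs are
#' merged and their evidence concatenated. Structural differences within the
#' shared span that match no single kind are emitted as kind `OTHER`.
#'
#' @param models a `transcript_set` whose transcript table carries `gene_id`
#' @param include_other emit unclassified complex regions as OTHER rows
#'   (default TRUE)
#' @return data.frame: kind, gene_id, chrom, strand, var_start, var_end,
#'   detail (variable-exon coordinates or shared-site tag, distinguishing
#'   same-span events of different composition), inclusion_ids,
#'   exclusion_ids, n_pairs
#' @export
enumerate_events <- function(models, include_other = TRUE) {
  tt <- tx_table(models)
  if (any(is.na(tt$gene_id))) stop("enumerate_events requires gene_id on every model")
  rows <- list()
  for (g in split(tt, tt$gene_id)) {
    if (nrow(g) < 2L) next
    if (length(unique(g$strand)) != 1L || length(unique(g$chrom)) != 1L)
      stop("mixed strands or chromosomes at locus ", g$gene_id[1L])
    ids <- sort(g$transcript_id)
    exs <- lapply(ids, function(id) exons_of(models, id))
    names(exs) <- ids
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (b <= a) next
      ev <- compare_pair(ids[a], ids[b], exs[[a]], exs[[b]], g$gene_id[1L])
      if (!is.null(ev)) rows[[length(rows) + 1L]] <- ev
      if (include_other) {
        oth <- other_regions(ids[a], ids[b], exs[[a]], exs[[b]], g$gene_id[1L], ev)
        if (!is.null(oth)) rows[[length(rows) + 1L]] <- oth
      }
    }
  }
  if (!length(rows))
    return(data.frame(kind = character(), gene_id = character(), chrom = character(),
                      strand = character(), var_start = integer(), var_end = integer(),
                      detail = character(), inclusion_ids = character(),
                      exclusion_ids = character(), n_pairs = integer(),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, rows)
  key <- paste(ev$kind, ev$gene_id, ev$chrom, ev$strand, ev$var_start, ev$var_end, ev$detail)
  merged <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    e <- ev[idx, , drop = FALSE]
    data.frame(kind = e$kind[1L], gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], var_start = e$var_start[1L], var_end = e$var_end[1L],
               detail = e$detail[1L],
               inclusion_ids = paste(sort(unique(e$inclusion)), collapse = ","),
               exclusion_ids = paste(sort(unique(e$exclusion)), collapse = ","),
               n_pairs = nrow(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene_id, out$var_start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exonic symmetric-difference regions within the shared span of a pair that
# no detected event accounts for -> complex/OTHER.
other_regions <- function(a_id, b_id, ra, rb, gene_id, detected) {
  span_lo <- max(min(ra$start), min(rb$start))
  span_hi <- min(max(ra$end), max(rb$end))
  if (span_hi <= span_lo) return(NULL)
  clip <- function(r) {
    ir <- IRanges::IRanges(pmax(r$start, span_lo) + 1L, pmin(r$end, span_hi))
    IRanges::reduce(ir[IRanges::width(ir) > 0L])
  }
  ca <- clip(ra); cb <- clip(rb)
  sdiff <- IRanges::union(IRanges::setdiff(ca, cb), IRanges::setdiff(cb, ca))
  sdiff <- IRanges::reduce(sdiff)
  if (!length(sdiff)) return(NULL)
  vs <- IRanges::start(sdiff) - 1L; ve <- IRanges::end(sdiff)
  keep <- rep(TRUE, length(sdiff))
  if (!is.null(detected) && nrow(detected)) {
    for (i in seq_along(sdiff))
      if (any(detected$var_start < ve[i] & vs[i] < detected$var_end)) keep[i] <- FALSE
  }
  if (!any(keep)) return(NULL)
  data.frame(kind = "OTHER", gene_id = gene_id, chrom = ra$chrom[1L],
             strand = ra$strand[1L], var_start = vs[keep], var_end = ve[keep],
             inclusion = a_id, exclusion = b_id, detail = "",
             stringsAsFactors = FALSE)
}

#' Frequency table of AS event kinds
#'
#' Percentages are computed over the six named kinds; OTHER (complex) regions
#' are counted but excluded from the percentage base.
#' @param events output of [enumerate_events()]
#' @return data.frame kind, count, pct (pct NA for OTHER)
#' @export
event_frequency_table <- function(events) {
  if (!nrow(events))
    return(data.frame(kind = character(), count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  cnt <- table(factor(events$kind, levels = c(EVENT_KINDS, "OTHER")))
  cnt <- cnt[cnt > 0L]
  base <- sum(cnt[names(cnt) %in% EVENT_KINDS])
  data.frame(kind = names(cnt), count = as.integer(cnt),
             pct = ifelse(names(cnt) %in% EVENT_KINDS,
                          100 * as.numeric(cnt) / base, NA_real_),
             stringsAsFactors = FALSE)
}

#' Tissue-specific AS event calls
#'
#' For each event and focal tissue, a 2x2 table (event count vs rest-of-gene
#' count; focal tissue vs pooled others) is tested with Fisher's exact
#' conditional test; the log2 fold-change compares depth-normalized event
#' rates (pseudocount 0.5). P-values are Benjamini-Hochberg adjusted across
#' the whole event-by-tissue grid. An event is tissue specific in a tissue
#' when its usage is at least eight-fold higher than in the other tissues
#' (log2 FC > 3) at adjusted p < 0.05.
#'
#' @param event_counts integer matrix, rows = events, columns = tissues
#' @param gene_totals matrix of the same shape: total counts of each event's
#'   host gene per tissue
#' @param fc_cutoff log2 fold-change cut-off (default 3)
#' @param p_cutoff adjusted-p cut-off (default 0.05)
#' @return data.frame: event_id, tissue, count, log2_fc, p_value,
#'   adj_p_value, tissue_specific. Degenerate rows (zero gene totals) are
#'   skipped with a message.
#' @export
tissue_specific_events <- function(event_counts, gene_totals,
                                   fc_cutoff = 3, p_cutoff = 0.05) {
  stopifnot(is.matrix(event_counts), identical(dim(event_counts), dim(gene_totals)))
  if (ncol(event_counts) < 2L) stop("need >= 2 tissues")
  ev_ids <- rownames(event_counts)
  if (is.null(ev_ids)) ev_ids <- paste0("event", seq_len(nrow(event_counts)))
  tissues <- colnames(event_counts)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(ncol(event_counts)))
  rows <- list(); n_skip <- 0L
  for (i in seq_len(nrow(event_counts))) for (t in seq_len(ncol(event_counts))) {
    a <- event_counts[i, t]; gt_f <- gene_totals[i, t]
    b <- sum(event_counts[i, -t]); gt_o <- sum(gene_totals[i, -t])
    if (gt_f <= 0 || gt_o <= 0) { n_skip <- n_skip + 1L; next }
    tab <- matrix(c(a, max(gt_f - a, 0), b, max(gt_o - b, 0)), nrow = 2L)
    p <- stats::fisher.test(round(tab))$p.value
    # pooled side uses the mean per-tissue rate so identical normalized
    # counts give a fold-change of exactly zero
    no <- ncol(event_counts) - 1L
    lfc <- log2(((a + 0.5) / gt_f) / ((b / no + 0.5) / (gt_o / no)))
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = ev_ids[i], tissue = tissues[t], count = a,
      log2_fc = lfc, p_value = p, stringsAsFactors = FALSE)
  }
  if (n_skip) message("tissue_specific_events: skipped ", n_skip,
                      " event-tissue pair(s) with zero gene totals")
  if (!length(rows))
    return(data.frame(event_id = character(), tissue = character(), count = numeric(),
                      log2_fc = numeric(), p_value = numeric(), adj_p_value = numeric(),
                      tissue_specific = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$tissue_specific <- out$log2_fc > fc_cutoff & out$adj_p_value < p_cutoff
  out
}
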