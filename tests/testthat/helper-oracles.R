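# Independent brute-force oracles. These re-derive every decision from the
# raw exon tables with plain loops, sharing no code with the package
# internals they check.

# ---- structural classification oracle ------------------------------------

# list-of-reference structure built by direct scans (no annotation_index)
oracle_ref <- function(ref) {
  tt <- split(ref$exons, ref$exons$transcript_id)
  gene_of <- stats::setNames(ref$transcripts$gene_id, ref$transcripts$transcript_id)
  txs <- lapply(names(tt), function(id) {
    r <- tt[[id]][order(tt[[id]]$start), ]
    n <- nrow(r)
    list(id = id, gene = gene_of[[id]], chrom = r$chrom[1], strand = r$strand[1],
         start = min(r$start), end = max(r$end), exons = r,
         introns = if (n > 1) cbind(r$end[-n], r$start[-1]) else matrix(0, 0, 2))
  })
  genes <- list()
  for (t in txs) {
    g <- t$gene
    if (is.null(genes[[g]]))
      genes[[g]] <- list(chrom = t$chrom, strand = t$strand, start = t$start, end = t$end)
    else {
      genes[[g]]$start <- min(genes[[g]]$start, t$start)
      genes[[g]]$end <- max(genes[[g]]$end, t$end)
    }
  }
  list(txs = txs, genes = genes)
}

oracle_classify <- function(exons, oref, mono_fsm_tol = 100) {
  r <- exons[order(exons$start), ]
  chrom <- r$chrom[1]; strand <- r$strand[1]
  n <- nrow(r)
  m_introns <- if (n > 1) cbind(r$end[-n], r$start[-1]) else matrix(0, 0, 2)
  m_start <- min(r$start); m_end <- max(r$end)
  same <- Filter(function(t) t$chrom == chrom && t$strand == strand, oref$txs)

  if (n > 1) {
    # FSM: identical intron chain
    for (t in same)
      if (nrow(t$introns) == n - 1 && all(t$introns == m_introns)) return("FSM")
    # ISM: contiguous sub-chain
    for (t in same) {
      k <- nrow(t$introns)
      if (k < n - 1) next
      for (off in 0:(k - (n - 1)))
        if (all(t$introns[(off + 1):(off + n - 1), , drop = FALSE] == m_introns))
          return("ISM")
    }
    # FUSION: junctions of >= 2 genomically separated genes
    hit_genes <- character()
    for (t in same) for (j in seq_len(nrow(t$introns)))
      for (l in seq_len(nrow(m_introns)))
        if (all(t$introns[j, ] == m_introns[l, ])) hit_genes <- c(hit_genes, t$gene)
    hit_genes <- unique(hit_genes)
    if (length(hit_genes) >= 2) {
      for (a in seq_along(hit_genes)) for (b in seq_along(hit_genes)) {
        if (b <= a) next
        ga <- oref$genes[[hit_genes[a]]]; gb <- oref$genes[[hit_genes[b]]]
        if (ga$end <= gb$start || gb$end <= ga$start) return("FUSION")
      }
    }
    # NIC: all donors and acceptors individually annotated
    ref_don <- ref_acc <- numeric()
    for (t in same) if (nrow(t$introns)) {
      if (strand == "+") { ref_don <- c(ref_don, t$introns[, 1]); ref_acc <- c(ref_acc, t$introns[, 2]) }
      else { ref_don <- c(ref_don, t$introns[, 2]); ref_acc <- c(ref_acc, t$introns[, 1]) }
    }
    m_don <- if (strand == "+") m_introns[, 1] else m_introns[, 2]
    m_acc <- if (strand == "+") m_introns[, 2] else m_introns[, 1]
    if (all(m_don %in% ref_don) && all(m_acc %in% ref_acc)) return("NIC")
    # NNC: exonic overlap with a same-strand gene
    for (t in same) for (j in seq_len(nrow(t$exons)))
      for (l in seq_len(n))
        if (t$exons$start[j] < r$end[l] && r$start[l] < t$exons$end[j]) return("NNC")
  } else {
    # mono-exon FSM / ISM by exon containment
    for (t in same) for (j in seq_len(nrow(t$exons))) {
      ex <- t$exons[j, ]
      if (ex$start <= m_start && m_end <= ex$end) {
        if (nrow(t$exons) == 1 && abs(ex$start - m_start) <= mono_fsm_tol &&
            abs(ex$end - m_end) <= mono_fsm_tol) return("FSM")
      }
    }
    for (t in same) for (j in seq_len(nrow(t$exons))) {
      ex <- t$exons[j, ]
      if (ex$start <= m_start && m_end <= ex$end) return("ISM")
    }
  }
  # GENIC_INTRON: whole model inside one same-strand annotated intron
  for (t in same) for (j in seq_len(nrow(t$introns)))
    if (t$introns[j, 1] <= m_start && m_end <= t$introns[j, 2]) return("GENIC_INTRON")
  # GENIC_GENOMIC: same-strand gene-body overlap
  for (g in oref$genes)
    if (g$chrom == chrom && g$strand == strand && g$start < m_end && m_start < g$end)
      return("GENIC_GENOMIC")
  # ANTISENSE: opposite-strand gene-body overlap
  for (g in oref$genes)
    if (g$chrom == chrom && g$strand != strand && g$start < m_end && m_start < g$end)
      return("ANTISENSE")
  "INTERGENIC"
}

# ---- AS-event oracle ------------------------------------------------------

# naive pairwise enumeration; returns kind/var_start/var_end rows
oracle_events_pair <- function(ra, rb) {
  ra <- ra[order(ra$start), ]; rb <- rb[order(rb$start), ]
  strand <- ra$strand[1]
  intr <- function(r) {
    n <- nrow(r)
    if (n < 2) return(matrix(0, 0, 2))
    cbind(r$end[-n], r$start[-1])
  }
  ia <- intr(ra); ib <- intr(rb)
  out <- list()
  add <- function(kind, vs, ve, detail = "") out[[length(out) + 1]] <<- data.frame(
    kind = kind, var_start = vs, var_end = ve, detail = detail,
    stringsAsFactors = FALSE)

  both <- list(list(ia, rb), list(ib, ra))
  for (pp in both) {
    ii <- pp[[1]]; other <- pp[[2]]
    for (j in seq_len(nrow(ii))) {
      s <- ii[j, 1]; e <- ii[j, 2]
      # IR
      for (l in seq_len(nrow(other)))
        if (other$start[l] < s && e < other$end[l]) add("IR", s, e)
      # ES / ME
      if (s %in% other$end && e %in% other$start) {
        ins <- which(other$start > s & other$end < e)
        if (length(ins) == 1)
          add("ES", other$start[ins], other$end[ins],
              paste0(other$start[ins], "-", other$end[ins]))
        if (length(ins) >= 2)
          add("ME", min(other$start[ins]), max(other$end[ins]),
              paste(other$start[ins], other$end[ins], sep = "-", collapse = ","))
      }
    }
  }
  # MX
  na <- nrow(ra); nb <- nrow(rb)
  for (d in intersect(ra$end[-na], rb$end[-nb]))
    for (acc in intersect(ra$start[-1], rb$start[-1])) {
      if (acc <= d) next
      ea <- which(ra$start > d & ra$end < acc)
      eb <- which(rb$start > d & rb$end < acc)
      if (!length(ea) || !length(eb)) next
      if (length(c(intersect(ra$start[ea], rb$start[eb]),
                   intersect(ra$end[ea], rb$end[eb])))) next
      disjoint <- TRUE
      for (x in ea) for (y in eb)
        if (ra$start[x] < rb$end[y] && rb$start[y] < ra$end[x]) disjoint <- FALSE
      if (!disjoint) next
      add("MX", min(ra$start[ea], rb$start[eb]), max(ra$end[ea], rb$end[eb]),
          paste(sort(c(paste(ra$start[ea], ra$end[ea], sep = "-"),
                       paste(rb$start[eb], rb$end[eb], sep = "-"))), collapse = ","))
    }
  # A5SS / A3SS
  for (j in seq_len(nrow(ia))) for (l in seq_len(nrow(ib))) {
    s1 <- ia[j, 1]; e1 <- ia[j, 2]; s2 <- ib[l, 1]; e2 <- ib[l, 2]
    if (e1 == e2 && s1 != s2) {
      rsh <- if (s1 < s2) rb else ra
      if (any(rsh$start <= min(s1, s2) & rsh$end >= max(s1, s2)))
        add(if (strand == "+") "A5SS" else "A3SS", min(s1, s2), max(s1, s2),
            paste0("J", e1))
    }
    if (s1 == s2 && e1 != e2) {
      rsh <- if (e1 > e2) rb else ra
      if (any(rsh$start <= min(e1, e2) & rsh$end >= max(e1, e2)))
        add(if (strand == "+") "A3SS" else "A5SS", min(e1, e2), max(e1, e2),
            paste0("J", s1))
    }
  }
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

oracle_events <- function(models) {
  tt <- tx_table(models)
  out <- list()
  for (g in split(tt, tt$gene_id)) {
    ids <- sort(g$transcript_id)
    if (length(ids) < 2) next
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (b <= a) next
      ev <- oracle_events_pair(exons_of(models, ids[a]), exons_of(models, ids[b]))
      if (!is.null(ev)) {
        ev$gene_id <- g$gene_id[1]
        out[[length(out) + 1]] <- ev
      }
    }
  }
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

# ---- ORF oracle -----------------------------------------------------------

# enumerate every ATG-initiated reading window, pick the longest
oracle_orf <- function(seq, min_aa = 100) {
  L <- nchar(seq)
  best <- NULL
  ch <- substring(seq, seq_len(L), seq_len(L))
  for (p in seq_len(max(L - 2, 0))) {
    if (!(ch[p] == "A" && ch[p + 1] == "T" && ch[p + 2] == "G")) next
    q <- p; aa <- 0; has_stop <- FALSE
    while (q + 2 <= L) {
      cod <- paste0(ch[q], ch[q + 1], ch[q + 2])
      if (cod %in% c("TAA", "TAG", "TGA") && q > p) { has_stop <- TRUE; break }
      aa <- aa + 1
      q <- q + 3
    }
    cand <- list(start = p - 1, aa_length = aa, has_stop = has_stop)
    if (is.null(best) || aa > best$aa_length ||
        (aa == best$aa_length && cand$start < best$start)) best <- cand
  }
  if (is.null(best) || best$aa_length < min_aa) return(NULL)
  best
}

# ---- flattening oracle ----------------------------------------------------

# per-nucleotide coverage signatures -> maximal runs
oracle_flatten <- function(exons) {
  lo <- min(exons$start); hi <- max(exons$end)
  sig <- character(hi - lo)
  for (p in seq_len(hi - lo)) {
    pos <- lo + p - 1
    cov <- sort(unique(exons$transcript_id[exons$start <= pos & pos < exons$end]))
    sig[p] <- paste(cov, collapse = ",")
  }
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- runs$values != ""
  data.frame(start = lo + starts[keep], end = lo + ends[keep],
             source_transcripts = runs$values[keep], stringsAsFactors = FALSE)
}
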