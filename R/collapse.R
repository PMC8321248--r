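#' Filter aligned models on alignment quality
#'
#' Retains models whose alignment identity and coverage both meet the
#' thresholds (boundary inclusive). Models without quality attributes are
#' retained with a warning, treated as pre-validated.
#'
#' @param models a `transcript_set` whose transcript table may carry
#'   `identity` and `coverage` columns in \[0,1\]
#' @param min_identity minimum alignment identity (default 0.95)
#' @param min_coverage minimum alignment coverage (default 0.99)
#' @return list: `models` (retained `transcript_set`), `dropped_low_quality`
#'   (character vector of dropped ids)
#' @export
filter_alignment_quality <- function(models, min_identity = 0.95, min_coverage = 0.99) {
  tx <- models$transcripts
  if (!nrow(tx))
    return(list(models = models, dropped_low_quality = character()))
  idn <- if ("identity" %in% names(tx)) tx$identity else rep(NA_real_, nrow(tx))
  cov <- if ("coverage" %in% names(tx)) tx$coverage else rep(NA_real_, nrow(tx))
  no_q <- is.na(idn) | is.na(cov)
  if (any(no_q))
    warning(sum(no_q), " model(s) lack alignment quality; retained as pre-validated")
  keep <- no_q | (idn >= min_identity & cov >= min_coverage)
  list(models = subset_transcripts(models, tx$transcript_id[keep]),
       dropped_low_quality = tx$transcript_id[!keep])
}

# 3'-anchored suffix test: is chain B (list of "s-e" intron tokens, genomic
# order) a contiguous 3'-anchored sub-chain of A? On the plus strand the 3'
# end is genomic-right, so B must equal the tail of A; on minus, the head.
chain_is_suffix <- function(chainA, chainB, strand) {
  ka <- length(chainA); kb <- length(chainB)
  if (kb > ka) return(FALSE)
  if (strand == "+") identical(chainA[(ka - kb + 1L):ka], chainB)
  else identical(chainA[1:kb], chainB)
}

#' Collapse aligned reads into a non-redundant isoform set
#'
#' Reads differing only by 5' truncation are treated as redundant: two
#' multi-exon models merge when their intron chains are identical, or when
#' one chain is a 3'-anchored contiguous suffix of the other (strand-aware)
#' and the two 3' terminal ends lie within `tol3` nt of each other. Within a
#' merged group the representative is the model with the greatest exonic
#' length (ties broken by lexicographically smallest id). Mono-exon reads are
#' clustered by single-linkage genomic overlap on the same strand;
#' optionally, mono-exon reads overlapping the 3' terminal exon of a
#' multi-exon representative are absorbed into it.
#'
#' @param models a `transcript_set` of aligned reads
#' @param tol3 3'-end tolerance in nt for suffix merging (default 100)
#' @param merge_mono_into_multi absorb mono-exon reads overlapping a
#'   multi-exon representative's terminal exon (default FALSE)
#' @return list of class `collapse_result`: `isoforms` (a `transcript_set` of
#'   representatives), `membership` (data.frame read_id -> isoform_id),
#'   `dropped_low_quality` (empty here; populated by callers that pre-filter)
#' @export
collapse_isoforms <- function(models, tol3 = 100L, merge_mono_into_multi = FALSE) {
  tt <- tx_table(models)
  if (!nrow(tt))
    return(structure(list(isoforms = models,
                          membership = data.frame(read_id = character(),
                                                  isoform_id = character(),
                                                  stringsAsFactors = FALSE),
                          dropped_low_quality = character()),
                     class = "collapse_result"))
  intr <- introns_table(models)
  chain_of <- split(paste(intr$start, intr$end, sep = "-"), intr$transcript_id)

  multi <- tt[tt$n_exons > 1L, , drop = FALSE]
  mono <- tt[tt$n_exons == 1L, , drop = FALSE]
  group_of <- character(0)   # read id -> group label

  # Multi-exon reads: two phases per chrom/strand locus. Phase 1 finds
  # maximal chains (unique chains not absorbed as a 3'-anchored suffix of a
  # longer chain within the 3' tolerance); phase 2 assigns every chain to a
  # maximal chain by following absorption pointers (nearest 3' end, then
  # most introns, then lexicographic — deterministic and order-invariant).
  # A read whose truncated chain fits several isoforms is thereby assigned
  # to exactly one without bridging them.
  for (grp in split(multi, paste(multi$chrom, multi$strand))) {
    strand <- grp$strand[1L]
    ir <- IRanges::IRanges(grp$start + 1L, grp$end)
    locus <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(ir, IRanges::reduce(ir)))
    for (loc in split(seq_len(nrow(grp)), locus)) {
      sub <- grp[loc, , drop = FALSE]
      ch <- chain_of[sub$transcript_id]
      key <- vapply(ch, paste, character(1L), collapse = ";")
      uniq <- !duplicated(key)
      ukey <- key[uniq]
      uch <- ch[uniq]
      # per unique chain: 3' end of its longest member (deterministic)
      end3 <- vapply(ukey, function(k) {
        mem <- sub[key == k, , drop = FALSE]
        mem <- mem[order(-mem$exonic_len, mem$transcript_id), ]
        if (strand == "+") mem$end[1L] else mem$start[1L]
      }, numeric(1L))
      ni <- lengths(uch)
      n_u <- length(ukey)
      parent_idx <- seq_len(n_u)
      if (n_u > 1L) {
        for (u in seq_len(n_u)) {
          best <- NULL
          for (v in seq_len(n_u)) {
            if (v == u || ni[v] <= ni[u]) next
            if (!chain_is_suffix(uch[[v]], uch[[u]], strand)) next
            d3 <- abs(end3[u] - end3[v])
            if (d3 > tol3) next
            cand <- c(d3, -ni[v], v)
            if (is.null(best) || d3 < best[1L] ||
                (d3 == best[1L] && ni[v] > ni[best[3L]]) ||
                (d3 == best[1L] && ni[v] == ni[best[3L]] && ukey[v] < ukey[best[3L]]))
              best <- cand
          }
          if (!is.null(best)) parent_idx[u] <- as.integer(best[3L])
        }
      }
      root <- function(i) { while (parent_idx[i] != i) i <- parent_idx[i]; i }
      roots <- vapply(seq_len(n_u), root, integer(1L))
      lab <- paste0(grp$chrom[1L], strand, ":", ukey[roots])
      group_of[sub$transcript_id] <- lab[match(key, ukey)]
    }
  }

  # mono-exon: single-linkage overlap clustering (same chrom/strand)
  for (grp in split(mono, paste(mono$chrom, mono$strand))) {
    ir <- IRanges::IRanges(grp$start + 1L, grp$end)
    comp <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(ir, IRanges::reduce(ir)))
    group_of[grp$transcript_id] <- paste0("mono:", grp$chrom[1L], grp$strand[1L], comp)
  }

  groups <- split(tt$transcript_id, group_of[tt$transcript_id])
  ck_all <- chain_keys(models)
  pick_rep <- function(ids, label) {
    # the representative carries the group's maximal chain (mono-exon
    # groups: any member); among those, greatest exonic length wins, ties
    # broken by lexicographically smallest id
    if (!startsWith(label, "mono:")) {
      full <- ids[!is.na(ck_all[ids]) & ck_all[ids] == label]
      if (length(full)) ids <- full
    }
    sub <- tt[match(ids, tt$transcript_id), , drop = FALSE]
    sub <- sub[order(-sub$exonic_len, sub$transcript_id), , drop = FALSE]
    sub$transcript_id[1L]
  }
  reps <- vapply(seq_along(groups), function(i)
    pick_rep(groups[[i]], names(groups)[i]), character(1L))
  membership <- data.frame(
    read_id = unlist(groups, use.names = FALSE),
    isoform_id = rep(reps, lengths(groups)),
    stringsAsFactors = FALSE)

  # optional absorption of mono-exon clusters into multi-exon representatives
  if (merge_mono_into_multi && nrow(mono) && nrow(multi)) {
    rep_multi <- reps[reps %in% multi$transcript_id]
    if (length(rep_multi)) {
      term <- do.call(rbind, lapply(rep_multi, function(id) {
        r <- exons_of(models, id)
        i <- if (r$strand[1L] == "+") nrow(r) else 1L
        data.frame(rep = id, chrom = r$chrom[i], strand = r$strand[i],
                   start = r$start[i], end = r$end[i], stringsAsFactors = FALSE)
      }))
      mono_reps <- reps[reps %in% mono$transcript_id]
      for (mr in mono_reps) {
        m <- tt[tt$transcript_id == mr, ]
        hit <- term[term$chrom == m$chrom & term$strand == m$strand &
                      term$start < m$end & m$start < term$end, , drop = FALSE]
        if (nrow(hit)) {
          membership$isoform_id[membership$isoform_id == mr] <- hit$rep[1L]
        }
      }
      reps <- unique(membership$isoform_id)
    }
  }

  structure(list(
    isoforms = subset_transcripts(models, unique(membership$isoform_id)),
    membership = membership[order(membership$read_id), , drop = FALSE],
    dropped_low_quality = character()),
    class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("collapse_result: %d reads -> %d isoforms (%d dropped low-quality)\n",
              nrow(x$membership), length(x$isoforms), length(x$dropped_low_quality)))
  invisible(x)
}
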