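#' Simulate a toy genome
#'
#' I.i.d. bases at the requested GC content; deterministic under `seed`.
#' @param n_chrom number of chromosomes
#' @param chrom_length length of each chromosome (recycled)
#' @param gc_fraction GC content in (0,1)
#' @param seed RNG seed
#' @return a `DNAStringSet` named chr1..chrN
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_length = 2e6, gc_fraction = 0.4,
                            seed = 1L) {
  stopifnot(n_chrom >= 1L, all(chrom_length > 0), gc_fraction > 0, gc_fraction < 1)
  set.seed(seed)
  chrom_length <- rep_len(as.integer(chrom_length), n_chrom)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(chrom_length, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
    character(1L))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

# overwrite genome[start,end) on chrom with seq (0-based half-open)
plant_sequence <- function(genome, chrom, start, seq) {
  Biostrings::subseq(genome[[chrom]], start + 1L, start + nchar(seq)) <-
    Biostrings::DNAString(seq)
  genome
}

# batched genome edits: record now, apply once per chromosome (first edit at
# a position wins; duplicates of identical ranges collapse)
apply_edits <- function(genome, edits) {
  if (!length(edits)) return(genome)
  df <- do.call(rbind, edits)
  for (chrom in unique(df$chrom)) {
    e <- df[df$chrom == chrom, , drop = FALSE]
    e <- e[!duplicated(e$start), , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(e)); last_end <- -1L
    for (i in seq_len(nrow(e))) {
      if (e$start[i] < last_end) keep[i] <- FALSE
      else last_end <- e$start[i] + nchar(e$value[i])
    }
    e <- e[keep, , drop = FALSE]
    genome[[chrom]] <- Biostrings::replaceAt(
      genome[[chrom]],
      IRanges::IRanges(e$start + 1L, e$start + nchar(e$value)),
      Biostrings::DNAStringSet(e$value))
  }
  genome
}

# transcript-orientation exon order
tx_order <- function(r) if (r$strand[1L] == "+") seq_len(nrow(r)) else rev(seq_len(nrow(r)))

#' Simulate an annotation with planted alternative-splicing events
#'
#' Each gene gets a base isoform (4-12 exons) plus derived isoforms, each
#' carrying one planted event drawn from `event_mix`. All splice sites are
#' written GT..AG into the genome (strand-aware) unless selected for the
#' non-canonical fraction. A polyA-signal hexamer drawn from `pas_mix` is
#' planted at a drawn distance upstream of each gene's 3' end (the sequence
#' between motif and cleavage site is scrubbed of accidental motifs; "none"
#' genes have their whole terminal window scrubbed). Each gene also gets an
#' A-rich 20-mer in its downstream intergenic flank (the intrapriming
#' relocation target) and one designated interior intron position carrying a
#' planted 8-nt direct repeat (the RT-switch target), both recorded in the
#' truth tables.
#'
#' @param genome a `DNAStringSet` from [simulate_genome()]; a modified copy
#'   is returned
#' @param n_genes number of genes
#' @param isoforms_per_gene mean isoforms per gene (1 base + Poisson-derived
#'   extras, at least 1 extra when the mean exceeds 1)
#' @param poisson_isoforms draw the number of derived isoforms per gene from
#'   a Poisson (default); FALSE gives every gene exactly
#'   `isoforms_per_gene - 1` derived isoforms
#' @param event_mix named probabilities over IR/ES/ME/MX/A3SS/A5SS (sums to 1)
#' @param pas_mix named probabilities over PAS hexamers and "none"
#' @param pas_distance integer vector of candidate motif-start-to-cleavage
#'   distances (default 10:30)
#' @param noncanonical_fraction fraction of introns given non-canonical
#'   dinucleotides (default 0)
#' @param seed RNG seed
#' @return list: `models` (a `transcript_set`), `genome` (edited copy),
#'   `truth` (lists of planted events, PAS, RT-switch sites, A-tract
#'   relocation targets, parameters)
#' @export
simulate_annotation <- function(genome, n_genes = 100L, isoforms_per_gene = 3,
                                event_mix = c(IR = 0.34, ES = 0.12, ME = 0.135,
                                              MX = 0.135, A3SS = 0.135, A5SS = 0.135),
                                pas_mix = c(AATAAA = 0.6, ATTAAA = 0.2, none = 0.2),
                                pas_distance = 10:30,
                                noncanonical_fraction = 0, seed = 1L,
                                poisson_isoforms = TRUE) {
  stopifnot(abs(sum(event_mix) - 1) < 1e-8,
            all(names(event_mix) %in% EVENT_KINDS))
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  set.seed(seed)
  # genes distributed over chromosomes proportional to length
  alloc <- round(n_genes * chrom_len / sum(chrom_len))
  alloc[1L] <- alloc[1L] + (n_genes - sum(alloc))
  margin <- 200L

  exon_rows <- list(); tx_rows <- list()
  ev_truth <- list(); pas_truth <- list(); rts_truth <- list(); atract_truth <- list()
  gi <- 0L
  edits <- list()
  add_edit <- function(chrom, start, value)
    edits[[length(edits) + 1L]] <<- data.frame(chrom = chrom, start = start,
                                               value = value,
                                               stringsAsFactors = FALSE)

  for (chrom in names(genome)) {
    ng <- alloc[[chrom]]
    if (ng <= 0L) next
    slot <- chrom_len[[chrom]] %/% ng
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      gene_id <- sprintf("G%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      slot_start <- (k - 1L) * slot
      avail <- slot - 2L * margin
      repeat {
        n_ex <- sample(4:12, 1L)
        el <- sample(80:300, n_ex, replace = TRUE)
        il <- sample(300:600, max(n_ex - 1L, 0L), replace = TRUE)
        span <- sum(el) + sum(il)
        if (span <= avail) break
        if (n_ex <= 4L) stop("chromosome too short for requested gene count")
      }
      g_start <- slot_start + margin +
        sample.int(max(avail - span, 1L), 1L) - 1L
      starts <- g_start + cumsum(c(0L, el[-n_ex] + il))
      base <- data.frame(start = starts, end = starts + el)
      g_end <- base$end[n_ex]

      # designated RT-switch intron = transcript-3'-most intron
      rts_idx <- if (strand == "+") n_ex - 1L else 1L
      rts_s <- base$end[rts_idx]; rts_e <- base$start[rts_idx + 1L]
      rts_alt <- rts_s + (rts_e - rts_s) %/% 2L

      # derived isoforms, each with one planted event
      n_derived <- if (isoforms_per_gene <= 1) 0L
        else if (!poisson_isoforms) as.integer(round(isoforms_per_gene - 1))
        else max(1L, stats::rpois(1L, isoforms_per_gene - 1))
      iso_list <- list(base)
      used <- character()       # (kind,pos) signatures already planted
      edited_introns <- rts_idx # genomic intron indices carrying planted edits
      d <- 0L; tries <- 0L
      while (d < n_derived && tries < 50L) {
        tries <- tries + 1L
        kind <- sample(names(event_mix), 1L, prob = event_mix)
        # transcript-internal positions, genome-edit conflicts avoided
        tx5_intron <- if (strand == "+") 1L else n_ex - 1L   # 5'-most intron (genomic idx)
        cand <- switch(kind,
          IR = setdiff(seq_len(n_ex - 1L), tx5_intron),
          ES = 2:(n_ex - 1L),
          ME = if (n_ex >= 4L) 2:(n_ex - 2L) else integer(),
          MX = setdiff(2:(n_ex - 1L), edited_introns),
          A3SS = , A5SS = setdiff(seq_len(n_ex - 1L), edited_introns))
        cand <- setdiff(cand, as.integer(sub("^.*:", "", grep(paste0("^", kind, ":"), used, value = TRUE))))
        if (!length(cand)) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        ex <- base; vs <- NA_integer_; ve <- NA_integer_
        if (kind == "IR") {
          vs <- base$end[j]; ve <- base$start[j + 1L]
          ex <- rbind(ex[seq_len(j - 1L), , drop = FALSE],
                      data.frame(start = base$start[j], end = base$end[j + 1L]),
                      if (j + 2L <= n_ex) ex[(j + 2L):n_ex, , drop = FALSE])
        } else if (kind == "ES") {
          vs <- base$start[j]; ve <- base$end[j]
          ex <- ex[-j, , drop = FALSE]
        } else if (kind == "ME") {
          vs <- base$start[j]; ve <- base$end[j + 1L]
          ex <- ex[-c(j, j + 1L), , drop = FALSE]
        } else if (kind == "MX") {
          # replace internal exon j by a new exon inside genomic intron j
          int_s <- base$end[j]; int_e <- base$start[j + 1L]
          len <- sample(80:120, 1L)
          ns <- int_s + 60L
          if (ns + len + 60L > int_e) next
          ex <- rbind(ex[seq_len(j - 1L), , drop = FALSE],
                      data.frame(start = ns, end = ns + len),
                      ex[(j + 1L):n_ex, , drop = FALSE])
          vs <- min(base$start[j], ns); ve <- max(base$end[j], ns + len)
          edited_introns <- c(edited_introns, j)
        } else {
          # A5SS/A3SS in transcript orientation: pick which genomic boundary
          # of intron j moves
          delta <- sample(30:60, 1L)
          move_start <- (kind == "A5SS") == (strand == "+")
          if (move_start) {        # extend exon j rightward into intron j
            vs <- base$end[j]; ve <- base$end[j] + delta
            ex$end[j] <- ex$end[j] + delta
          } else {                 # extend exon j+1 leftward
            vs <- base$start[j + 1L] - delta; ve <- base$start[j + 1L]
            ex$start[j + 1L] <- ex$start[j + 1L] - delta
          }
          edited_introns <- c(edited_introns, j)
        }
        d <- d + 1L
        used <- c(used, paste0(kind, ":", j))
        iso_list[[length(iso_list) + 1L]] <- ex
        ev_truth[[length(ev_truth) + 1L]] <- data.frame(
          gene_id = gene_id, isoform_id = sprintf("%s.%d", gene_id, d + 1L),
          kind = kind, chrom = chrom, strand = strand,
          var_start = vs, var_end = ve, stringsAsFactors = FALSE)
      }

      for (m in seq_along(iso_list)) {
        iso_id <- sprintf("%s.%d", gene_id, m)
        r <- iso_list[[m]]
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          transcript_id = iso_id, chrom = chrom, start = r$start, end = r$end,
          strand = strand, stringsAsFactors = FALSE)
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = iso_id, gene_id = gene_id, stringsAsFactors = FALSE)
      }

      # --- genome edits -------------------------------------------------
      # canonical (or selected non-canonical) dinucleotides at every intron
      all_introns <- unique(do.call(rbind, lapply(iso_list, function(r) {
        n <- nrow(r)
        if (n < 2L) return(NULL)
        data.frame(s = r$end[-n], e = r$start[-1L])
      })))
      for (ii in seq_len(nrow(all_introns))) {
        noncanon <- stats::runif(1L) < noncanonical_fraction
        s <- all_introns$s[ii]; e <- all_introns$e[ii]
        if (strand == "+") {
          add_edit(chrom, s, if (noncanon) "GG" else "GT")
          add_edit(chrom, e - 2L, if (noncanon) "GG" else "AG")
        } else {
          add_edit(chrom, s, if (noncanon) "CC" else "CT")
          add_edit(chrom, e - 2L, if (noncanon) "CC" else "AC")
        }
      }

      # RT-switch direct repeat planted inside the designated intron
      # donor-side k-mer is exonic and untouched by the other edits, so it
      # can be read from the pre-edit genome
      if (strand == "+") {
        donor_kmer <- fetch_sequence(genome, chrom, rts_s - 8L, rts_s)
        add_edit(chrom, rts_alt - 8L, donor_kmer)
      } else {
        donor_kmer <- fetch_sequence(genome, chrom, rts_e, rts_e + 8L)
        add_edit(chrom, rts_alt, donor_kmer)
      }
      rts_truth[[length(rts_truth) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = chrom, strand = strand,
        intron_start = rts_s, intron_end = rts_e, alt_pos = rts_alt,
        stringsAsFactors = FALSE)

      # polyA signal upstream of the gene's 3' end
      motif <- sample(names(pas_mix), 1L, prob = pas_mix)
      dist <- if (length(pas_distance) == 1L) pas_distance else sample(pas_distance, 1L)
      if (motif == "none") {
        if (strand == "+") add_edit(chrom, g_end - 50L, strrep("C", 50L))
        else add_edit(chrom, g_start, strrep("G", 50L))
        dist <- NA_integer_
      } else {
        if (strand == "+") {
          add_edit(chrom, g_end - dist, motif)
          if (dist > 6L) add_edit(chrom, g_end - (dist - 6L), strrep("C", dist - 6L))
        } else {
          add_edit(chrom, g_start + dist - 6L, revcomp(motif))
          if (dist > 6L) add_edit(chrom, g_start, strrep("G", dist - 6L))
        }
      }
      pas_truth[[length(pas_truth) + 1L]] <- data.frame(
        gene_id = gene_id, motif = motif, distance = dist, stringsAsFactors = FALSE)

      # immediate downstream flank of the TTS: fixed 25% A composition so a
      # clean 3' end never looks intraprimed
      flank <- paste(sample(rep(c("A", "C", "G", "T"), 5L)), collapse = "")
      if (strand == "+") add_edit(chrom, g_end, flank)
      else add_edit(chrom, g_start - 20L, flank)

      # A-rich intrapriming relocation target in the downstream flank
      off <- sample(30:60, 1L)
      if (strand == "+") {
        reloc <- g_end + off
        add_edit(chrom, reloc, strrep("A", 20L))
      } else {
        reloc <- g_start - off
        add_edit(chrom, reloc - 20L, strrep("T", 20L))
      }
      atract_truth[[length(atract_truth) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = chrom, strand = strand, reloc_pos = reloc,
        stringsAsFactors = FALSE)
    }
  }

  genome <- apply_edits(genome, edits)
  models <- transcript_set(do.call(rbind, exon_rows), do.call(rbind, tx_rows))
  list(models = models, genome = genome,
       truth = list(events = if (length(ev_truth)) do.call(rbind, ev_truth) else NULL,
                    pas = do.call(rbind, pas_truth),
                    rts_sites = do.call(rbind, rts_truth),
                    atract = do.call(rbind, atract_truth),
                    params = list(n_genes = n_genes, event_mix = event_mix,
                                  pas_mix = pas_mix,
                                  noncanonical_fraction = noncanonical_fraction,
                                  seed = seed)))
}

#' Simulate long reads from a simulated annotation
#'
#' Each read copies a source isoform. With probability `p_truncate` its 5'
#' end is cut by a geometric number of nt (whole 5' exons dropped when the
#' cut crosses a junction; at least one intron is always retained). With
#' probability `p_rts` the designated RT-switch intron, when present in the
#' source, is shortened to the planted direct-repeat acceptor. With
#' probability `p_intraprime` the 3' end is relocated to the gene's planted
#' A-rich tract. By default the first read of every isoform is emitted
#' full-length so the true isoform set is recoverable by collapsing.
#'
#' @param sim output of [simulate_annotation()]
#' @param n_reads number of reads
#' @param p_truncate probability of 5' truncation
#' @param trunc_mean geometric mean truncation length in nt (default 300)
#' @param p_intraprime probability of the intrapriming artifact
#' @param p_rts probability of the RT-switch artifact
#' @param seed RNG seed
#' @param ensure_full_length guarantee one clean full-length read per isoform
#'   before random sampling (default TRUE)
#' @return list: `reads` (a `transcript_set`), `truth` (data.frame read_id,
#'   source_isoform, truncation, intraprime, rts)
#' @export
simulate_long_reads <- function(sim, n_reads, p_truncate = 0.5, trunc_mean = 300,
                                p_intraprime = 0, p_rts = 0, seed = 1L,
                                ensure_full_length = TRUE) {
  stopifnot(p_truncate >= 0, p_truncate <= 1, p_intraprime >= 0, p_intraprime <= 1,
            p_rts >= 0, p_rts <= 1)
  models <- sim$models
  set.seed(seed)
  ids <- models$transcripts$transcript_id
  gene_of <- stats::setNames(models$transcripts$gene_id, ids)
  rts <- sim$truth$rts_sites
  atract <- sim$truth$atract
  n_guaranteed <- if (ensure_full_length) min(length(ids), n_reads) else 0L
  sources <- c(ids[seq_len(n_guaranteed)],
               if (n_reads > n_guaranteed)
                 sample(ids, n_reads - n_guaranteed, replace = TRUE))

  exon_rows <- list(); truth_rows <- list()
  for (i in seq_len(n_reads)) {
    src <- sources[i]
    r <- exons_of(models, src)
    strand <- r$strand[1L]; chrom <- r$chrom[1L]
    clean <- i <= n_guaranteed
    did_rts <- FALSE; did_ip <- FALSE; cut <- 0L

    if (!clean && stats::runif(1L) < p_rts) {
      site <- rts[rts$gene_id == gene_of[[src]], ]
      if (nrow(site)) {
        if (strand == "+") {
          j <- which(r$start == site$intron_end)
          j <- j[j > 1L & r$end[j - 1L] == site$intron_start]
          if (length(j)) { r$start[j[1L]] <- site$alt_pos; did_rts <- TRUE }
        } else {
          j <- which(r$end == site$intron_start)
          j <- j[j < nrow(r) & r$start[j + 1L] == site$intron_end]
          if (length(j)) { r$end[j[1L]] <- site$alt_pos; did_rts <- TRUE }
        }
      }
    }
    if (!clean && stats::runif(1L) < p_intraprime) {
      tr <- atract[atract$gene_id == gene_of[[src]], ]
      if (nrow(tr)) {
        if (strand == "+") r$end[nrow(r)] <- tr$reloc_pos
        else r$start[1L] <- tr$reloc_pos
        did_ip <- TRUE
      }
    }
    if (!clean && nrow(r) > 1L && stats::runif(1L) < p_truncate) {
      ord <- tx_order(r)
      lens <- (r$end - r$start)[ord]
      cap <- sum(lens[-length(lens)]) - 1L   # keep the 3'-most intron
      cut <- min(stats::rgeom(1L, 1 / trunc_mean), max(cap, 0L))
      t_rem <- cut
      drop <- integer()
      for (j in seq_along(ord)) {
        if (t_rem >= lens[j] && j < length(ord)) {
          drop <- c(drop, ord[j]); t_rem <- t_rem - lens[j]
        } else break
      }
      if (length(drop)) r <- r[-drop, , drop = FALSE]
      if (t_rem > 0L) {
        if (strand == "+") r$start[1L] <- r$start[1L] + t_rem
        else r$end[nrow(r)] <- r$end[nrow(r)] - t_rem
      }
    }
    read_id <- sprintf("read%05d", i)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      transcript_id = read_id, chrom = chrom, start = r$start, end = r$end,
      strand = strand, stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      read_id = read_id, source_isoform = src, truncation = cut,
      intraprime = did_ip, rts = did_rts, stringsAsFactors = FALSE)
  }
  reads <- transcript_set(do.call(rbind, exon_rows))
  # reads are exact exon-chain copies: perfect alignment quality
  reads$transcripts$identity <- 1
  reads$transcripts$coverage <- 1
  list(reads = reads, truth = do.call(rbind, truth_rows))
}

#' Simulate a short-read splice-junction support table
#'
#' Each junction receives Poisson(`depth`) unique-read support, except a
#' `dropout` fraction (drawn per junction) which receives 0.
#'
#' @param junctions data.frame chrom, strand, start, end (e.g. from
#'   [introns_table()])
#' @param depth mean unique-read support
#' @param dropout probability a junction is left unsupported
#' @param seed RNG seed
#' @return junction table as from [read_junction_table()]
#' @export
simulate_junction_table <- function(junctions, depth = 20, dropout = 0, seed = 1L) {
  stopifnot(depth > 0)
  jx <- unique(junctions[, c("chrom", "strand", "start", "end")])
  set.seed(seed)
  n <- nrow(jx)
  sup <- stats::rpois(n, depth)
  sup[stats::runif(n) < dropout] <- 0L
  data.frame(chrom = jx$chrom, start = jx$start, end = jx$end,
             strand = jx$strand, unique_read_support = as.integer(sup),
             stringsAsFactors = FALSE)
}

#' Simulate per-bin read counts with planted usage shifts
#'
#' Per gene and sample, a gene total is drawn negative-binomially around
#' `baseline_depth` (exactly `baseline_depth` when `dispersion` is 0) and
#' distributed multinomially over the gene's bins with probabilities
#' proportional to bin width; in condition B, planted bins have their weight
#' multiplied by 2^shift.
#'
#' @param bins bin table from [flatten_gene_models()]
#' @param samples_per_condition samples in each of the two conditions
#' @param baseline_depth mean gene total per sample
#' @param planted_effects data.frame (bin_id, log2_shift), or NULL
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 means fixed totals
#' @param seed RNG seed
#' @return list: `counts` (matrix bins x samples), `condition` (factor),
#'   `truth` (the planted_effects table)
#' @export
simulate_bin_counts <- function(bins, samples_per_condition = 3L,
                                baseline_depth = 500, planted_effects = NULL,
                                dispersion = 0.05, seed = 1L) {
  force(bins); force(planted_effects)
  set.seed(seed)
  n_s <- 2L * samples_per_condition
  condition <- factor(rep(c("A", "B"), each = samples_per_condition))
  samples <- paste0(condition, rep(seq_len(samples_per_condition), 2L))
  counts <- matrix(0L, nrow = nrow(bins), ncol = n_s,
                   dimnames = list(bins$bin_id, samples))
  shift <- stats::setNames(rep(0, nrow(bins)), bins$bin_id)
  if (!is.null(planted_effects))
    shift[planted_effects$bin_id] <- planted_effects$log2_shift
  for (g in split(seq_len(nrow(bins)), bins$gene_id)) {
    w <- (bins$end - bins$start)[g]
    wB <- w * 2^shift[bins$bin_id[g]]
    for (s in seq_len(n_s)) {
      tot <- if (dispersion > 0)
        stats::rnbinom(1L, mu = baseline_depth, size = 1 / dispersion)
      else as.integer(baseline_depth)
      pr <- if (condition[s] == "A") w else wB
      counts[g, s] <- stats::rmultinom(1L, tot, pr / sum(pr))[, 1L]
    }
  }
  list(counts = counts, condition = condition, truth = planted_effects)
}
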