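# diverse random models against a simulated annotation: every structural
# situation the classifier distinguishes, plus pure noise
random_models <- function(sim, n, seed) {
  set.seed(seed)
  ref <- sim$models
  tt <- tx_table(ref)
  chrom_len <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  rows <- list()
  for (i in seq_len(n)) {
    kind <- sample(c("copy", "subchain", "skip", "shift", "fusion",
                     "in_intron", "straddle", "antisense", "random"), 1,
                   prob = c(.2, .15, .12, .12, .08, .08, .08, .08, .09))
    tx <- tt[sample(nrow(tt), 1), ]
    r <- exons_of(ref, tx$transcript_id)
    m <- NULL
    if (kind == "copy") {
      m <- r
    } else if (kind == "subchain" && nrow(r) >= 3) {
      a <- sample(nrow(r) - 1, 1); b <- min(nrow(r), a + sample(1:3, 1))
      m <- r[a:b, ]
      m$start[1] <- m$start[1] + sample(0:20, 1)
      m$end[nrow(m)] <- m$end[nrow(m)] - sample(0:20, 1)
    } else if (kind == "skip" && nrow(r) >= 4) {
      m <- r[-sample(2:(nrow(r) - 1), 1), ]
    } else if (kind == "shift" && nrow(r) >= 3) {
      m <- r
      j <- sample(2:(nrow(r) - 1), 1)
      m$start[j] <- m$start[j] - sample(3:6, 1)
    } else if (kind == "fusion") {
      g2 <- tt[tt$gene_id != tx$gene_id & tt$strand == tx$strand &
                 tt$chrom == tx$chrom, ]
      if (nrow(g2)) {
        r2 <- exons_of(ref, g2$transcript_id[sample(nrow(g2), 1)])
        if (min(r2$start) > max(r$end) || min(r$start) > max(r2$end))
          m <- rbind(r, r2)[order(c(r$start, r2$start)), ]
      }
    } else if (kind == "in_intron" && nrow(r) >= 2) {
      j <- sample(nrow(r) - 1, 1)
      s <- r$end[j]; e <- r$start[j + 1]
      if (e - s > 80) {
        m <- r[1, ]
        m$start <- s + 20; m$end <- e - 20
      }
    } else if (kind == "straddle") {
      j <- sample(nrow(r), 1)
      m <- r[1, ]
      m$start <- (r$start[j] + r$end[j]) %/% 2
      m$end <- m$start + 150
    } else if (kind == "antisense") {
      m <- r
      m$strand <- if (r$strand[1] == "+") "-" else "+"
    }
    if (is.null(m)) {           # fallback / pure noise
      L <- chrom_len[[1]]
      s <- sample(L - 2000, 1)
      m <- data.frame(transcript_id = "x", chrom = names(chrom_len)[1],
                      start = s, end = s + sample(200:800, 1),
                      strand = sample(c("+", "-"), 1))
    }
    m$transcript_id <- sprintf("m%05d", i)
    rows[[i]] <- m[, c("transcript_id", "chrom", "start", "end", "strand")]
  }
  transcript_set(do.call(rbind, rows))
}

# random locus with arbitrary structural perturbations (not only clean
# planted kinds) to stress the pairwise comparison
random_locus <- function(n_iso, n_exons, seed) {
  set.seed(seed)
  el <- sample(60:150, n_exons, replace = TRUE)
  il <- sample(200:400, n_exons - 1, replace = TRUE)
  starts <- 1000 + cumsum(c(0, el[-n_exons] + il))
  base <- data.frame(start = starts, end = starts + el)
  strand <- sample(c("+", "-"), 1)
  spec <- list(i1 = list(chrom = "c1", strand = strand, gene = "g",
                         exons = lapply(seq_len(n_exons), function(i) c(base$start[i], base$end[i]))))
  for (k in seq_len(n_iso - 1)) {
    ex <- base
    for (op in seq_len(sample(1:2, 1))) {
      what <- sample(c("skip", "retain", "shift_d", "shift_a", "insert"), 1)
      n <- nrow(ex)
      if (what == "skip" && n >= 3) {
        ex <- ex[-sample(2:(n - 1), 1), ]
      } else if (what == "retain" && n >= 2) {
        j <- sample(n - 1, 1)
        ex <- rbind(ex[seq_len(j - 1), , drop = FALSE],
                    data.frame(start = ex$start[j], end = ex$end[j + 1]),
                    if (j + 2 <= n) ex[(j + 2):n, , drop = FALSE])
      } else if (what == "shift_d" && n >= 2) {
        j <- sample(n - 1, 1)
        ex$end[j] <- ex$end[j] + sample(10:40, 1)
      } else if (what == "shift_a" && n >= 2) {
        j <- sample(n - 1, 1)
        ex$start[j + 1] <- ex$start[j + 1] - sample(10:40, 1)
      } else if (what == "insert" && n >= 2) {
        j <- sample(n - 1, 1)
        gap_s <- ex$end[j]; gap_e <- ex$start[j + 1]
        if (gap_e - gap_s >= 150) {
          ns <- gap_s + 50
          ex <- rbind(ex[seq_len(j), , drop = FALSE],
                      data.frame(start = ns, end = ns + 50),
                      ex[(j + 1):n, , drop = FALSE])
        }
      }
    }
    spec[[paste0("i", k + 1)]] <- list(chrom = "c1", strand = strand, gene = "g",
                                       exons = lapply(seq_len(nrow(ex)),
                                                      function(i) c(ex$start[i], ex$end[i])))
  }
  make_ts(spec)
}
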