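# Small in-code fixtures shared across tests.

# genome from explicit chromosome strings
make_genome <- function(...) {
  seqs <- list(...)
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# transcript_set from a compact spec: list(id = list(chrom, strand, exons =
# list(c(s,e), ...), gene = NULL))
make_ts <- function(spec) {
  ex <- do.call(rbind, lapply(names(spec), function(id) {
    s <- spec[[id]]
    em <- do.call(rbind, s$exons)
    data.frame(transcript_id = id, chrom = s$chrom, start = em[, 1],
               end = em[, 2], strand = s$strand, stringsAsFactors = FALSE)
  }))
  tx <- data.frame(
    transcript_id = names(spec),
    gene_id = vapply(spec, function(s) if (is.null(s$gene)) NA_character_ else s$gene,
                     character(1L)),
    stringsAsFactors = FALSE)
  transcript_set(ex, tx)
}

# random base string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
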