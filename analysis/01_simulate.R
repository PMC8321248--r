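#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system — a 2 Mb genome, 100 multi-isoform
# genes with planted AS events, polyA signals, artifact targets — and the read
# sets used by the later stages. Everything is written under results/ with
# its truth tables so each stage is checkable.

suppressMessages(library(isoscan))
dir.create("results", showWarnings = FALSE)

seed <- 2024L
genome <- simulate_genome(n_chrom = 1, chrom_length = 2e6, gc_fraction = 0.4,
                          seed = seed)
sim <- simulate_annotation(genome, n_genes = 100, isoforms_per_gene = 3,
                           seed = seed)
message(sprintf("simulated %d isoforms across %d genes (%d planted AS events)",
                length(sim$models), nrow(sim$truth$pas), nrow(sim$truth$events)))

# clean + truncated long reads (the collapse input)
reads <- simulate_long_reads(sim, n_reads = 1000, p_truncate = 0.5, seed = seed + 1)
# artifact-bearing reads (the filter input)
reads_art <- simulate_long_reads(sim, n_reads = 500, p_truncate = 0,
                                 p_intraprime = 0.1, p_rts = 0.1,
                                 seed = seed + 2, ensure_full_length = FALSE)
jt <- simulate_junction_table(introns_table(sim$models), depth = 20,
                              seed = seed + 3)

Biostrings::writeXStringSet(sim$genome, "results/genome.fa")
write_gtf(sim$models, "results/annotation.gtf")
write_gtf(reads$reads, "results/reads.gtf")
write_gtf(reads_art$reads, "results/reads_artifact.gtf")
write_junction_table(jt, "results/SJ.out.tab")
for (nm in c("events", "pas", "rts_sites", "atract"))
  utils::write.table(sim$truth[[nm]], sprintf("results/truth_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(reads$truth, "results/truth_reads.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(reads_art$truth, "results/truth_reads_artifact.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/genome.fa, annotation.gtf, reads*.gtf, SJ.out.tab and truth tables")
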