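#!/usr/bin/env Rscript
# Stage 2: collapse the 5'-truncated reads into a non-redundant isoform set
# and classify every isoform against the reference annotation; verify the
# collapse against the simulation truth.

suppressMessages(library(isoscan))

genome <- read_genome("results/genome.fa")
reference <- read_annotation("results/annotation.gtf")
reads <- read_annotation("results/reads.gtf")   # exon chains in GTF form
truth <- utils::read.table("results/truth_reads.tsv", header = TRUE, sep = "\t")

cr <- collapse_isoforms(reads)
true_chains <- unique(stats::na.omit(chain_keys(reference)))
rec_chains <- unique(stats::na.omit(chain_keys(cr$isoforms)))
message(sprintf("collapsed %d reads -> %d isoforms; true chain recovery %.1f%%",
                nrow(cr$membership), length(cr$isoforms),
                100 * length(intersect(rec_chains, true_chains)) /
                  length(union(rec_chains, true_chains))))

ann <- annotation_index(reference)
calls <- classify_transcripts(cr$isoforms, ann, genome)
tab <- table(calls$category)
message("structural categories: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))
jx <- classify_junctions(cr$isoforms, genome, ann)
message(sprintf("junctions: %d, canonical %.1f%%, known %.1f%%",
                nrow(jx), 100 * mean(jx$canonical), 100 * mean(jx$known)))

write_gtf(cr$isoforms, "results/isoforms.gtf")
utils::write.table(cr$membership, "results/membership.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(calls, "results/classification.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(jx, "results/junctions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
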