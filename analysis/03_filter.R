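#!/usr/bin/env Rscript
# Stage 3: artifact filtration of the artifact-bearing read set —
# intrapriming (downstream A-fraction), RT-switch direct repeats, and novel
# junctions without short-read support — scored against the planted truth.

suppressMessages(library(isoscan))

genome <- read_genome("results/genome.fa")
reference <- read_annotation("results/annotation.gtf")
reads <- read_annotation("results/reads_artifact.gtf")
jt <- read_junction_table("results/SJ.out.tab")
truth <- utils::read.table("results/truth_reads_artifact.tsv", header = TRUE, sep = "\t")

ann <- annotation_index(reference)
fr <- filter_isoforms(reads, genome, ann, jt)
rep <- fr$report[match(truth$read_id, fr$report$isoform_id), ]
is_art <- truth$intraprime | truth$rts
called <- rep$intrapriming | rep$rts_flag
message(sprintf("filter: removed %d / %d reads; artifact sensitivity %.1f%%, FPR %.2f%%",
                sum(rep$disposition == "removed"), nrow(rep),
                100 * mean(called[is_art]), 100 * mean(called[!is_art])))
utils::write.table(fr$report, "results/filter_report.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_gtf(fr$kept, "results/isoforms_filtered.gtf")
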