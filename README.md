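# isoscan

Structural characterization of full-length transcript isoforms from
long-read (Iso-Seq style) sequencing, as an R package plus a reproducible
analysis workflow. Long cDNA reads observe whole isoforms but carry
systematic artifacts — 5'-truncated molecules from incomplete reverse
transcription, false 3' ends from oligo(dT) intrapriming in genomic A-rich
tracts, and spurious junctions from reverse-transcriptase template switching
at direct repeats. `isoscan` implements the standard downstream pipeline:

* **collapse** — merge reads whose intron chains are identical or
  3'-anchored suffixes of one another (within a 100 nt 3' tolerance) and
  keep the longest isoform per group;
* **classify** — assign each isoform one of nine structural categories
  against a reference annotation (FSM, ISM, NIC, NNC, Fusion, Genic
  Genomic, Genic Intron, Antisense, Intergenic), type every junction
  (canonical GT-AG/GC-AG/AT-AC, strand-corrected; known vs novel), and
  compute signed distances of isoform ends to annotated TSS/TTS;
* **filter** — remove intrapriming candidates (A-fraction >= 0.6 in the
  20 nt downstream of the 3' end), RT-switch candidates (exact 8-mer direct
  repeat across a junction) and novel junctions lacking short-read support
  (SJ.out.tab dialect);
* **AS events** — enumerate intron retention, exon skipping, multiple exon
  skips, mutually exclusive exons and alternative 5'/3' splice sites by
  pairwise isoform comparison, with frequencies and tissue-specific calls
  (log2 FC > 3, adjusted p < 0.05, Fisher + Benjamini-Hochberg);
* **polyA / ORF** — scan the 3'-terminal 50 nt for 12 polyadenylation-signal
  hexamers (closest to cleavage wins), call longest ORFs (>= 100 aa) and
  flag putative non-coding transcripts (> 200 nt, no qualifying ORF);
* **exon usage** — flatten gene models into disjoint counting bins, count
  reads per bin, and test usage ratios (bin vs rest of gene) between two
  conditions with an exact conditional test.

A first-class synthetic-data module (`simulate_genome`,
`simulate_annotation`, `simulate_long_reads`, `simulate_junction_table`,
`simulate_bin_counts`) generates toy genomes with planted AS events, PAS
motifs, artifact targets and usage shifts, each with a machine-readable
truth table, so every stage is tested against known answers — no downloads
needed.

## Worked example

```r
library(isoscan)

genome <- simulate_genome(1, 2e6, 0.4, seed = 7)
sim    <- simulate_annotation(genome, n_genes = 100, seed = 7)   # ~300 isoforms
reads  <- simulate_long_reads(sim, 1000, p_truncate = 0.5, seed = 8)

collapsed <- collapse_isoforms(reads$reads)
collapsed
#> collapse_result: 1000 reads -> 301 isoforms (0 dropped low-quality)

ann   <- annotation_index(sim$models)
calls <- classify_transcripts(collapsed$isoforms, ann, sim$genome)
table(calls$category)
#> FSM
#> 301
```

Every truncated read was reassigned to its source isoform: the 301
recovered intron chains equal the 301 simulated ones exactly, and each
recovered isoform is a full splice match (FSM) to the annotation with zero
terminal distance. The numbered scripts under `analysis/`
(`01_simulate.R` ... `05_exon_usage.R`) run the same system end to end —
simulation, collapse + classification, artifact filtration, AS/PAS/ORF
analysis, differential exon usage — printing what each stage found and
writing its tables under `results/`.

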