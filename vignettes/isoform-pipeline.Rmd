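---
title: "Characterizing full-length transcript isoforms: models, rules and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing full-length transcript isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscan)
```

## The problem

Single-molecule long-read cDNA sequencing (Iso-Seq and kin) reads whole
transcripts, so isoform structure — the exact chain of exons — is observed
directly rather than assembled. The price is a set of systematic artifacts:
incomplete reverse transcription truncates molecules from the 5' end,
oligo(dT) primers anneal inside genomic A-rich tracts and fake 3' ends
(intrapriming), and reverse transcriptase jumps across direct repeats and
fabricates splice junctions (RT switching). `isoscan` implements the
standard downstream workflow for such data: collapse redundant reads into a
non-redundant isoform set, classify each isoform structurally against a
reference annotation, filter artifacts, enumerate alternative-splicing (AS)
events, scan for polyadenylation signals (PAS), call ORFs and non-coding
candidates, and test differential exon usage — with a synthetic-data module
that generates toy genomes with machine-readable truth, so every rule is
testable without external data.

Internally every coordinate is 0-based half-open; GTF/GFF3 and the SJ.out.tab
junction dialect are converted at the I/O boundary. Splice-site
dinucleotides and all distances are reported in transcript orientation, so
GT-AG is canonical on both strands and negative terminal distances always
mean "upstream of the reference end".

## Collapsing 5'-truncated reads

Two multi-exon reads are redundant when their intron chains are identical,
or when the shorter chain is a contiguous 3'-anchored suffix of the longer
one (a genomic prefix on the minus strand) and the two 3' termini agree
within a tolerance, 100 nt by default — polyA cleavage wobbles, so exact
3'-end equality would be too strict. Only 5' truncation is collapsed,
because incomplete retrotranscription specifically erodes 5' ends;
3'-truncated chains remain separate isoforms.

The algorithm works in two phases per locus. First it finds *maximal*
chains: unique chains not absorbed as a 3'-anchored suffix of any longer
chain within the tolerance. Then it assigns every read to a maximal chain by
following absorption pointers (nearest 3' end, then most introns, then
lexicographic order). The point of the second phase is an ambiguity that a
naive single-linkage merge gets wrong: a severely truncated read whose
remaining chain fits *several* isoforms of a locus must be assigned to one
of them, not allowed to bridge them into a single cluster. The
representative of each group is the longest member that carries the group's
maximal chain (ties broken by smallest id); a truncated-but-exonically-long
member (e.g. a read from an intron-retaining isoform) can otherwise outrank
the full-structure reads. Collapse is idempotent and invariant to input
order. Mono-exon reads are clustered separately by single-linkage genomic
overlap; merging them into multi-exon representatives is available behind a
flag (default off) because upstream tools differ on this behavior.

## Structural classification

Each isoform gets exactly one category, decided by a fixed precedence that
orders the categories from most to least specific:

1. **FSM** — intron chain identical to a reference transcript;
2. **ISM** — chain a contiguous sub-chain of a reference chain (both 5'- and
   3'-anchored sub-chains are accepted);
3. **FUSION** — junctions hit annotated junctions of two or more genomically
   non-overlapping genes (overlapping genes count as one locus, which avoids
   spurious fusions in dense regions);
4. **NIC** — every donor and acceptor individually annotated but the chain
   novel;
5. **NNC** — at least one unannotated splice site, with same-strand exonic
   overlap;
6. **GENIC_INTRON** — wholly inside one annotated intron, same strand;
7. **GENIC_GENOMIC** — partial same-strand gene overlap;
8. **ANTISENSE** — only opposite-strand overlap;
9. **INTERGENIC** — otherwise.

Mono-exon models match FSM when contained in a mono-exon reference exon with
both ends within 100 nt, and ISM when contained in any reference exon. Gene
association for NIC/NNC picks the same-strand gene sharing most junctions,
ties broken by exonic overlap. Terminal distances (`dist5`, `dist3`) are
signed in transcript orientation: positive means the isoform end lies
downstream of the reference TSS/TTS. The whole procedure is checked against
an independently coded brute-force classifier on a thousand randomized
models per run; agreement is exact.

## Artifact filtration

Three rules, composed disjunctively (any failure removes the isoform, and
every removal carries a machine-readable reason):

* **Intrapriming** — the fraction of genomic adenines in the 20 nt
  immediately downstream of the 3' end, read in transcript orientation.
  The flag threshold is 0.6: far above the ~0.25-0.3 background of a
  40% GC genome and comfortably below the >=0.8 signature of genuine
  oligo(dT) mispriming, so both error rates are small.
* **RT switching** — an exact direct repeat of length 8 between the k-mer
  ending at the donor boundary (last exonic bases) and the k-mer ending at
  the acceptor boundary inside the intron. Eight exact bases make a chance
  match on one junction about 4^-8, negligible at pipeline scale.
* **Short-read support** — a novel junction with fewer than 1 unique
  supporting reads in the SJ.out.tab table removes its isoform; FSM
  isoforms are exempt since all their junctions are annotated. A
  strand-undefined table row supports either strand.

## AS events, PAS, ORFs

AS events are defined pairwise: for every isoform pair of a locus, variable
regions bounded by shared splice sites are classified as intron retention
(IR: one isoform's intron interior to the other's exon), exon skipping (ES,
one exon) or multiple exon skips (ME, >= 2), mutually exclusive exons (MX:
disjoint internal exon sets between shared flanks), or alternative 5'/3'
splice sites (named in transcript orientation). Identical events from
different pairs merge with concatenated evidence; regions matching no single
kind are emitted as OTHER and excluded from the six-way percentages.
Pairwise definitions were chosen over a splice-graph formulation because
they are directly checkable against exhaustive enumeration, which the test
suite does on hundreds of randomized loci. Note a consequence worth knowing:
two single-exon-skipping isoforms of the same gene, compared with each
other, legitimately evidence an MX event.

Tissue specificity of an event uses a 2x2 exact conditional test (event
count vs rest-of-gene count, focal tissue vs pooled others) with
Benjamini-Hochberg adjustment across the whole event-by-tissue grid; an
event is tissue specific at log2 fold-change > 3 (eight-fold) and adjusted
p < 0.05. The fold-change compares the focal depth-normalized rate with the
*mean* per-tissue rate of the others (pseudocount 0.5), so identical
normalized counts give exactly zero.

PAS scanning reads the 3'-terminal 50 nt of each spliced isoform and looks
for 12 literature hexamers (AATAAA, ATTAAA and ten common single-base
variants); every window position is examined, overlapping occurrences
included, and the hit closest to the cleavage site is the primary call,
distance counted from motif start to cleavage. ORFs are longest-ATG calls
over the three forward frames, 3'-partial ORFs admitted; the operative
thresholds are >= 100 aa for coding and spliced length > 200 nt for
putative non-coding (ORF-less transcripts at or below 200 nt are
"short/unclassified"). Hidden-Markov gene scoring and external
coding-potential databases are out of scope; the length gates are the
defined rules here.

## Differential exon usage

Gene models are flattened into disjoint counting bins by projecting all exon
boundaries; adjacent fragments covered by the same transcript set merge, and
bins touching a second gene's exons are flagged ambiguous and left untested.
Reads (spliced interval chains) increment every bin they overlap by at least
1 nt, unstranded by default since short-read protocols vary. Counts are
pooled within each of two conditions and each bin is tested on the 2x2
table bin-vs-rest-of-gene by condition with Fisher's exact conditional
test; log2 fold-change is the ratio of usage ratios with pseudocount 0.5;
BH adjustment runs across all tested bins of the experiment; bins under 10
total reads are excluded. This pooled exact test replaces the
negative-binomial GLM machinery of dedicated DEU packages on purpose: the
operative quantity is the usage ratio and its fold-change/adjusted-p
thresholds, which this fully specified statistic delivers, and the
acceptance surface is parameter recovery on synthetic data (null
false-positive fraction <= 5%, >= 80% power for a log2 shift of 3 at
per-gene depth 500). Replicate-aware dispersion estimation is a future
extension, not silently approximated.

## The synthetic study system

`simulate_genome` draws i.i.d. bases (default 1 chromosome x 2 Mb, GC 0.4).
`simulate_annotation` places genes in disjoint slots (no placement
collisions by construction): each gene is a base isoform of 4-12 exons
(exons 80-300 nt, introns 300-600 nt) plus derived isoforms — about 3
isoforms per gene by default — each carrying one planted event drawn from a
configurable kind mixture whose default is IR-dominated (34% IR, 12% ES,
rest uniform), the shape long-read studies report. The generator edits the
genome so the data carry their own evidence:

* GT..AG dinucleotides (strand-aware) at every splice site, with an optional
  non-canonical fraction;
* a PAS hexamer from a configurable mixture (default 60% AATAAA / 20%
  ATTAAA / 20% none) at a drawn distance (10-30 nt) upstream of each TTS —
  the sequence between motif and cleavage site is rewritten to C so no
  accidental motif sits closer than the planted one, and "none" genes have
  the whole 50-nt window scrubbed;
* a 20-mer of fixed 25% A composition immediately downstream of each TTS,
  so clean 3' ends never look intraprimed;
* an A-rich 20-mer in the intergenic flank 30-60 nt downstream of each TTS:
  the relocation target for simulated intrapriming (reads move their 3' end
  there instead of editing the genome per read, keeping the genome the
  single source of truth);
* an 8-mer copy of the donor-boundary sequence at the midpoint of one
  designated intron per gene (the transcript-3'-most, which 5' truncation
  cannot remove): the RT-switch target. The repeat sits inside the intron,
  so clean isoforms are unaffected.

`simulate_long_reads` copies a source isoform per read and applies 5'
truncation (geometric, mean 300 nt, whole exons dropped when the cut
crosses a junction; at least one intron is always retained so no read
degenerates to mono-exon), intrapriming relocation, and RT-switch junction
shortening, all recorded per read in a truth table. Two generator choices
matter for interpretation. First, planted IR never sits on the
transcript-5'-most intron: an isoform differing from another only by
retaining that intron is *inherently* indistinguishable from a 5'-degraded
read under the collapse rule, so a benchmark that demands exact recovery
must not plant it (real data do contain such cases, and there they are
genuinely ambiguous). Second, by default the first read of every isoform is
emitted full-length; recovery of the true isoform set is only an
identifiability property when every isoform is actually observed intact at
least once. Both switches are exposed (`ensure_full_length`, the event
position rules) and the tests exercise the defaults.

What the simulation does *not* emulate: base-call errors and indels (reads
are exon chains, not base calls), expression-level variation among isoforms,
overlapping gene loci, alternative TSS/TTS wobble, and genome-wide repeat
structure. Passing tests therefore demonstrate that the rules are
implemented exactly as specified and recover planted structure under clean
and artifact-bearing channels — not that thresholds like the 0.6 A-fraction
are optimal on real tissues.

## Problem sizes and numerics

The shipped analyses and checks run at: 100 genes / ~300 isoforms / 2 Mb for
classification (1,000 randomized models against the annotation), collapse
(1,000 reads), artifact recovery (500 reads), and junction typing; 200
random loci for AS-oracle equivalence; 1,000 single-isoform genes for the
PAS mixture; 200 genes x 2 conditions x 3 samples at per-gene depth 500
(negative-binomial dispersion 0.05) for usage calibration and power. All
simulators take explicit seeds and regenerate byte-identically; Fisher tests
and BH adjustment come from base R's `stats`. Ties are broken
deterministically everywhere (lexicographic ids, leftmost ORF, most-introns
absorption), so every pipeline output is a pure function of inputs and
seeds.
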