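Package: isoscan
Title: Structural Characterization of Long-Read Transcript Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for full-length transcript isoforms derived
    from long-read (Iso-Seq style) sequencing: collapsing of 5'-degraded
    redundant reads into a non-redundant isoform set, structural
    classification against a reference annotation (FSM/ISM/NIC/NNC and the
    genic/intergenic categories), splice-junction typing (canonical
    GT-AG/GC-AG/AT-AC; known versus novel), filtration of intrapriming and
    reverse-transcriptase template-switching artifacts and of novel junctions
    lacking short-read support, enumeration of alternative-splicing events
    (intron retention, exon skipping, multiple exon skips, mutually exclusive
    exons, alternative 5'/3' splice sites), polyadenylation-signal scanning,
    longest-ORF prediction with non-coding flagging, and differential exon
    usage over collapsed exon counting bins. A synthetic-data module
    generates toy genomes, annotations, reads with planted artifacts,
    junction tables and count matrices with machine-readable truth, so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
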