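Package: microDNAseq
Title: Split-Read Identification and Characterization of microDNA from
    Circle-Enriched Sequencing Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Base-pair-resolution identification of microDNA (small
    extrachromosomal circular DNA) junctions from paired-end alignments of
    rolling-circle-amplified, circle-enriched sequencing libraries. A read
    pair supports a circle when one mate maps uniquely inside the circle
    and the other is a split (soft-clipped plus supplementary) read whose
    two parts mark the circle's two genomic edges in inverted query order.
    Includes a synthetic-data generator (toy genome, planted circle length
    mixtures, paired-end reads drawn from circular templates, and an
    oracle aligner emitting SAM so no external aligner is needed),
    subsampling-based library-complexity estimation, and genomic
    characterization of call sets: feature enrichment relative to a
    length-preserving random-placement null, length distributions with
    nucleosome-periodicity detection, and GC content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Coverage, Software
RoxygenNote: 7.3.3
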