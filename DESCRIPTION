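Package: gatcseq
Title: Single-GATC Resolution DamID-seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational readout for DamID-seq experiments that sequence
    directly from DpnI-cut adenine-methylated GATC sites. Builds a genome-wide
    GATC cut-site index from FASTA, filters aligned paired-end reads down to
    those whose first read originates exactly at a DpnI blunt cut, counts
    methylation events per GATC, quantifies tagmentation-end uniqueness,
    compares samples (Pearson correlation over all genomic GATCs, log-ratio
    normalisation to an unfused Dam control, top-site ranking, signal
    matrices), measures spatial resolution (methylation decay around peak
    midpoints with half-decay distance, and binned genome-wide
    autocorrelation), estimates locus-specific methylated fractions from
    DpnI/DpnII qPCR cycle counts, and ships a generative simulator of the
    whole assay (focal methylation with exponential distance decay,
    processive extension across adjacent GATCs, open-chromatin background,
    non-specific ligation reads, tagmentation fragment lengths and PCR
    duplicates) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
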