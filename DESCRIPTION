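Package: TranscriptMarkers
Title: Marker Discovery and Genotype Analysis for Multi-Line Transcriptome
    Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for molecular-marker development from de novo
    transcriptome assemblies of inbred crop lines. Mines simple sequence
    repeats (SSRs) with mixed-motif merging and cross-line redundancy
    removal, discovers single nucleotide polymorphisms (SNPs) from
    multi-sample read pileups with a probe-design filter ladder
    (homopolymer, indel and contig-end distance criteria), computes
    genotyping-array statistics (allele frequencies, residual versus
    expected heterozygosity under selfing, exact binomial excess tests),
    post-processes homology-search tabular output (best-hit filtering,
    contamination screening, sliding-window density mapping), and ships a
    deterministic simulator of multi-line transcripts, 454-style reads and
    genotype matrices for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, Alignment, VariantDetection
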