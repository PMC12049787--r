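Package: ASoCkit
Title: Allele-Specific Open Chromatin Calling, Allelic Motif Scoring, and
    Dual-Species Co-Culture Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping allele-specific open chromatin (ASoC) from
    ATAC-seq allelic read counts at heterozygous SNPs: per-sample genotype and
    depth filtering, cross-sample aggregation, exact two-sided binomial
    testing, Benjamini-Hochberg false-discovery-rate control, open-chromatin
    peak annotation, and Monte-Carlo power analysis.  Also scores allelic
    disruption of transcription-factor binding motifs around a SNP with
    position weight matrices, and performs negative-binomial differential
    expression for mixed human/mouse co-culture RNA-seq using per-sample
    species read totals as a cellular-composition correction factor.  Seeded
    simulators generate ground-truthed allelic count tables, peak intervals,
    motif windows, and dual-species count matrices so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    cluster
biocViews: Epigenetics, ATACSeq, RNASeq, DifferentialExpression, SNP,
    Transcription, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'ASoCkit-package.R'
    'AllClasses.R'
    'asoc-calling.R'
    'cli.R'
    'coculture-de.R'
    'io.R'
    'motif-scoring.R'
    'power.R'
    'simulate-asoc.R'
    'simulate-coculture.R'
    'simulate-motif.R'
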