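Package: svqtl
Title: Structural-Variant QTL Discovery in Multiparental Doubled-Haploid
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An inference chain for discovering and validating small
    structural variants (30 bp - 26 kb deletions and insertions) that
    modulate flowering time in multiparental doubled-haploid (DH) crop
    populations. Covers marker quality control and SNaP
    (single nucleotide absence polymorphism) calling from systematic
    array call failure, kinship- and structure-adjusted single-marker
    association scans with Benjamini-Hochberg FDR control,
    D'-confidence-interval (Gabriel) linkage-disequilibrium blocks for
    QTL delineation, SV-gene-promoter intersection with a
    flowering-gene keyword filter, chi-square segregation tests,
    in-silico PCR product-size prediction, normalized-mean-coverage
    (NMC) deletion genotyping from per-base read depth, per-environment
    allelic-effect estimation, and JASPAR position-frequency-matrix
    motif scanning of deleted sequence. A synthetic multiparental DH
    population generator (Haldane meiosis, configurable ancestral
    haplotype blocks, multi-environment phenotypes with GxE, depth
    tracks with deletion dropout) reproduces the statistical structure
    every downstream stage assumes, so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'assoc.R'
    'io.R'
    'ldblocks.R'
    'markers.R'
    'pipeline.R'
    'simulate.R'
    'svcat.R'
    'svgeno.R'
    'svqtl-package.R'
    'tfbs.R'
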