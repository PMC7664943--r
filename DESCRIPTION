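Package: texmap
Title: Trans-Ancestral Exclusion Mapping and Epigenetic Prioritization of
    GWAS Risk Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Refines an extended GWAS risk haplotype to a core haplotype
    shared across ancestries and prioritizes the surviving tag-SNPs by
    layered functional annotation. Implements QC filtering, two-locus EM
    linkage-disequilibrium estimation, solid-spine haplotype block
    detection and inter-block merging, tag-SNP selection, allelic
    case/control association with fixed- and random-effects meta-analysis,
    trans-ancestral exclusion mapping (cross-ancestry MAF/OR discordance
    rules), scored-interval annotation overlap with a 25-bp edge-averaging
    rule, chromatin-interaction membership, and allele-specific
    transcription-factor binding via position-weight-matrix log-odds
    scanning with an exact score-distribution stringency threshold. A
    seeded simulator plants multi-population panels with a shared core
    risk haplotype, phenotypes, annotation tracks and motif fixtures so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
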