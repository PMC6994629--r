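Package: twaspleio
Title: Transcriptome-Wide Association and Cross-Trait Pleiotropy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level transcriptome-wide association analysis (TWAS):
    imputation of genetically regulated gene expression from genotype dosages
    and per-tissue eQTL prediction weights, covariate-adjusted association of
    imputed expression with case/control status, joint false-discovery-rate
    control across all gene-tissue tests, and classification of hits against
    known GWAS loci. Also implements cross-trait pleiotropy analysis via
    LD-defined R-squared loci (r2 > 0.5 around GWAS lead variants), locus
    merging, gene-locus overlap, and Fisher-exact category enrichment, plus
    gene-set overrepresentation with a rank-deviation combined score. A
    synthetic-data module generates LD-blocked dosage panels, sparse cis
    weight models, liability-threshold case/control cohorts, and multi-trait
    GWAS catalogs so the full pipeline is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
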