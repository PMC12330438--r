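Package: svsieve
Title: Rare Structural Variant Discovery, Curation and Burden Analysis in Family Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sieving rare structural variants (deletions and
    insertions >= 50 bp) out of long-read family cohorts. Implements
    truvari-style SV matching (breakpoint distance, reciprocal size
    similarity, sequence identity), within-sample callerset validation,
    inter-sample collapse into a nonredundant genotype matrix,
    pangenome-control allele-presence filtering with sex-matched
    comparisons, six-category rare-SV classification, stepwise
    transmission curation of Mendelian-violating calls (relaxed rematch,
    callable-region score, genotyper support, tandem-repeat allele
    comparison, read support), interval-track functional annotation,
    proband-sibling burden statistics (rate-ratio chi-square,
    Mann-Whitney U), pangenome discovery curves, sex-chromosome assembly
    window-coverage statistics, and haplotype-resolved CpG-island
    methylation / X-inactivation skew. A fully deterministic synthetic
    cohort generator with a planted-truth ledger supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
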