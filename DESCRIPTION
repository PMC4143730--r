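Package: supervar
Title: Singleton Collapsing and Gene-Based Rare-Variant Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association analysis of rare variants from
    case-control sequencing cohorts. Collapses the singletons of each gene
    into a per-sample binary supervariant, tests genes with three
    permutation-based rare-variant statistics (linear-kernel SSU/SKAT,
    C-alpha, and CMC with Hotelling's T2), applies a two-step adaptive
    permutation scan with a Bonferroni gene-based threshold, stratifies
    signal by CDS/UTR/intron region, characterises the supervariant with
    exact 2x2 inference (Fisher p, conditional-MLE odds ratio, exact CI),
    and checks population stratification with principal-component-adjusted
    logistic regression. Includes a synthetic cohort generator with a
    singleton-rich site-frequency spectrum, a configurable carrier-level
    odds ratio and optional two-subpopulation confounding, plus VCF,
    refFlat and phenotype readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
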