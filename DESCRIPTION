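Package: ylineage
Title: Y-Chromosome Lineage Analysis: SNP Discovery Filters, Haplogroup
    Classification, Median-Joining Networks, Rho-Statistic Dating, AMOVA
    and Multiple Correspondence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-genetic analysis of Y-chromosome lineage
    data. Implements candidate Y-SNP discovery filtering (transversion,
    repeat-mask, known-catalog and proximity-window rules), hierarchical
    haplogroup classification against a user-supplied or packaged Q-M3
    marker tree, weighted median-joining Y-STR haplotype networks,
    modal-ancestral-haplotype rho-statistic TMRCA dating under configurable
    mutation-rate calibrations, two-level hierarchical analysis of
    molecular variance (AMOVA) with permutation significance, and multiple
    correspondence analysis of SNP states. A synthetic-data module
    simulates star and two-level structured male genealogies with Y-STR
    loci evolving under the symmetric single-step stepwise mutation model
    and biallelic SNPs nested on genealogy branches, so every stage of the
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
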