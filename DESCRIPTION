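Package: trioburden
Title: De Novo Mutation Burden, Paralog Clustering and Trio Filtering for
    Exome Studies of Rare Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for trio-based de novo mutation studies:
    Mendelian filtering of trio variant calls with read-support and parental
    coverage rules, KING-robust verification of biological parentage,
    exact-binomial mosaicism assessment from allele fractions, gene-set de
    novo burden testing against gene-specific mutation rates (Poisson tail),
    two-sided Fisher case-control carrier comparison, a permutation test for
    clustering of mutations across paralogous genes in aligned protein
    coordinates (with an analytic exact counterpart for small instances),
    HGVS-style cDNA-to-protein coordinate mapping, and phenotype
    summarisation. Includes a synthetic-data generator for trio cohorts with
    planted de novo events and for paralog families with known true
    alignments, so every stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
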