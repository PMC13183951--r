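Package: GeneticNurture
Title: Genetic Nurture Analysis via Transmitted and Non-Transmitted Polygenic Scores
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haplotype-based inference of transmitted and non-transmitted
    parental alleles in genotyped parent-offspring trios and pairs, polygenic
    score decomposition into transmitted (PGS_T) and non-transmitted (PGS_NT)
    components, family-clustered mixed models separating direct genetic
    transmission from genetic nurture, longitudinal PGS-by-age models,
    parent-of-origin path models with full-information maximum likelihood and
    cluster-robust Wald tests, bootstrap mediation through parental
    phenotypes, and Monte Carlo power analysis for parent-of-origin
    contrasts. Includes a synthetic family-cohort simulator (founder
    haplotypes, meiosis with recombination, pair/trio masking, phenotypes
    under a known generative model) so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
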