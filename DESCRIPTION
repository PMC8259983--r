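Package: meallocate
Title: Growth-Coupled Metabolism-and-Expression Models with Coenzyme
    Activity Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A miniature metabolism-and-expression (ME) modeling framework
    for studying condition-dependent proteome and cofactor allocation.
    Builds mu-parametric stoichiometric models with the full set of
    growth-coupled expression constraints (ribosome, RNA polymerase,
    synthetase, enzyme, tRNA and mRNA coupling), extends them with a
    pseudo-kinetic coenzyme-activity coupling that forces coenzyme
    biosynthesis in proportion to coenzyme use, and maximizes growth rate
    by bisection over linear-programming feasibility. Includes biomass
    constituent demand accounting (amino acids, prosthetic groups,
    coenzymes) with growth-rate and protein-biomass normalizations,
    multi-condition nutrient scans, composition statistics (PCA, outlier
    calling, Ward clustering with gap-statistic model selection, rank-sum
    cluster characterization), auxotroph nutrient-limitation profiles with
    subsystem protein allocation, and a seeded generator of toy ME
    networks for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
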