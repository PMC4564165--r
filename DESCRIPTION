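Package: irdprior
Title: Recessive Variant Prioritization for Consanguineous Retinal
    Degeneration Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Candidate-variant discovery for autosomal recessive inherited
    retinal degeneration (IRD) in consanguineous pedigrees. Implements
    per-site quality screening, homozygosity-based recessive filtering, an
    eight-rule annotation filter cascade (population homozygote frequency,
    transcribed-region and UTR rules, missense predictor consensus, splice
    distance rules, transcript biotype), restriction to a known-IRD gene
    panel, pedigree co-segregation verification, screening against
    ethnicity-matched controls, and a cohort-level catalog of recurrent
    population-unique variants. Ships a seeded synthetic-cohort generator
    (pedigrees with consanguinity loops, autozygous causal variants planted
    by Mendelian gene-dropping, decoy variants spanning every filter class)
    so the whole pipeline is testable without patient exomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    jsonlite,
    stats,
    utils,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
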