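Package: gwasim
Title: Simulation and Benchmarking of GWAS Methods in Diverse and Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time, resampling-based simulation of case-control
    genome-wide association study (GWAS) cohorts for homogeneous and multi-way
    admixed populations, together with an in-package battery of association
    scoring statistics and evaluation tools. Synthetic multi-population
    reference haplotype panels are generated under a Balding-Nichols model
    with a founder-copying process that induces local linkage disequilibrium;
    cohorts are produced by recombination-aware resampling with exact
    local-ancestry tract tracking, logistic multi-locus penetrance, and
    optional case-control ancestry deviation in risk regions. Association
    tests include trend and logistic regression, EMMAX-style linear mixed
    models (with and without leave-one-chromosome-out relatedness matrices),
    Laplace-approximation Bayes factors, local-ancestry-aware joint tests,
    admixture mapping, and a posterior-probability-of-association
    combination. Cross-population replication is evaluated with fixed-,
    random-, and binary-effects meta-analysis with per-study m-values, and
    power / false-positive-rate reports are assembled over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
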