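Package: gsmass
Title: Genomic and Phenotypic Mass Selection for Allogamous Crops
Version: 0.1.0
Authors@R: person("Avery", "Morton", email = "avery.morton@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time simulation and analysis of recurrent mass
    selection in self-incompatible allogamous crops such as common buckwheat.
    Implements a yield-predictive selection index fitted by principal
    component regression with leave-one-out cross-validation, per-trait
    genomic prediction by G-BLUP (with the equivalent ridge-regression
    marker-effect representation), a two-cycle-per-year genomic selection
    scheme with annual model updating and marker-panel attrition, pairwise
    linkage disequilibrium estimation including an EM algorithm for dominant
    markers, LD-based effective population size estimation from the
    Hill-Weir drift expectation, and population comparison by Welch's t-test
    with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
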