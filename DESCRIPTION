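Package: mrlipids
Title: Mendelian Randomization of Alcohol Consumption on Lipid Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for Mendelian-randomization analysis of
    alcohol consumption on blood lipid measures using an unweighted
    genetic risk score built from alcohol-dehydrogenase gene variants.
    Provides deterministic derivation of lipid phenotypes (Friedewald
    LDL-c, HDL subfractions, isoform-corrected Lp(a), log transforms),
    screening of candidate instrument SNPs against instrumental-variable
    assumptions (linkage disequilibrium with lipid loci, confounder
    correlation, pairwise redundancy pruning), manual two-stage least
    squares with a quartiled nonlinear second stage and Wald tests,
    weak-instrument diagnostics (first-stage F and partial R-squared),
    sensitivity reruns over drinker-status exclusions, and a synthetic
    cohort generator that emulates the statistical structure of a large
    European-American epidemiological cohort so the whole pipeline is
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
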