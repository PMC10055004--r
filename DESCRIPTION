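Package: strataxis
Title: Stratification-Aware Polygenic Score Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and correcting stratification bias in tests of
    association between polygenic scores and axes of ancestry. Implements a
    direct estimator of the single axis of GWAS-panel population structure that
    confounds a given polygenic score association test, built from test-panel
    genotype contrasts, alongside the standard principal-component correction.
    Includes frequency-level simulators for tree and stepping-stone demographies
    with independent biallelic sites, phenotype simulators with controlled
    environmental confounding and heritable architectures, vectorised marginal
    association scans, polygenic scoring, a standardized F4 statistic with its
    predicted-bias formula, random-matrix accuracy theory for sample principal
    components, and replicate-based error decompositions for structure
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
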