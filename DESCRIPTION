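Package: gxefam
Title: Gene-by-Environment Interaction Analysis in Family-Based Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates genotyped family cohorts (monozygotic and dizygotic
    twins, siblings and their parents) with polygenic indices for cognitive
    and noncognitive skills, passive gene-environment correlation and seven
    educational outcomes, and estimates polygenic-index-by-socioeconomic-status
    interactions under three designs: between-family regression, within-family
    (family fixed effects) sibling comparison, and the trio design controlling
    for both parents' polygenic indices. Provides family-clustered sandwich
    standard errors, Bonferroni and Romano-Wolf step-down bootstrap corrections
    for the seven-outcome test family, analytic minimum-detectable incremental
    R-squared and Monte-Carlo power analysis, and a pipeline that runs the full
    2 polygenic indices x 7 outcomes x 3 designs grid with sign and
    significance tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    jsonlite
Config/testthat/edition: 3
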