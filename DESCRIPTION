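Package: paleosex
Title: Proteomic, Genomic, and Osteological Sex Estimation for Archaeological Cohorts
Version: 0.1.0
Authors@R:
    person("paleosex", "maintainers", email = "maintainers@paleosex.org", role = c("aut", "cre"))
Description: Three-track biological sex estimation for archaeological skeletal
    cohorts. Computes the Ry statistic (Y-mapped reads over all sex-chromosome
    reads) and the Rx statistic (X-chromosome read rate relative to each
    autosome) with 95% confidence intervals from samtools-idxstats style count
    tables, classifying karyotype into definitive, conditional and indeterminate
    tiers; filters amelogenin peptide tables for AMELX/AMELY specificity,
    normalizes cumulative ion intensities per mg enamel and evaluates a
    four-parameter logistic probability of female sex; ingests expert
    osteological trait estimates. Includes cross-method concordance accounting,
    read-depth threshold stratification, preservation statistics, a synthetic
    cohort generator with age-dependent DNA decay, and a packaged 55-sample
    reference cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
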