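Package: smrlink
Title: Summary-Data Mendelian Randomization Linking GWAS Traits to
    Molecular QTLs
Version: 0.1.0
Authors@R:
    person("smrlink", "developers", email = "smrlink@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for summary-data Mendelian
    randomization (SMR). Reads GWAS and cis-QTL (expression or
    methylation) summary statistics from flat files, harmonizes effect
    alleles across datasets, selects the top cis-QTL SNP per probe as an
    instrument, and tests whether a molecular phenotype mediates a
    SNP-trait association with the approximate chi-square(1) SMR
    statistic. Includes gene-overlap and methylation-QTL cross-reference
    stages for multi-trait integration, a synthetic summary-statistics
    generator with known ground truth for calibration and recovery
    testing, and a command-line entry point orchestrating the full
    workflow.
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
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
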