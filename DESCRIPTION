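Package: signalmr
Title: Dual-Evidence Drug Safety Analysis with Disproportionality Signals and Drug-Target Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for dual-evidence drug
    safety assessment. One arm reads FAERS-style quarterly spontaneous-report
    tables, deduplicates cases by the standard CASEID/FDA_DT/PRIMARYID rule,
    and computes four disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with chi-square, the empirical Bayes
    geometric mean under a two-gamma-mixture gamma-Poisson shrinker, and the
    Bayesian confidence propagation information component) under full-database
    and within-class reporting backgrounds, with gender and age
    stratification. The other arm performs cis-region drug-target Mendelian
    randomization from GWAS summary statistics: p-value and LD-clumping
    instrument selection, allele harmonization, and five estimators (IVW,
    MR-Egger, weighted median, simple mode, weighted mode) with a
    positive-control validation step. Seeded synthetic-data generators for
    both report tables and two-sample GWAS summary statistics make every
    stage verifiable at desk scale with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
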