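Package: sexmeta
Title: Sex-Combined Joint Main and SNP-by-Sex Interaction Tests for GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Association testing for genome-wide association studies in the
    presence of sex-specific genetic effects. Implements the omnibus
    quadratic meta-analysis that combines sex-stratified z-statistics into a
    2-df chi-square joint test of SNP main and SNP-by-sex interaction
    effects, alongside the traditional inverse-variance-weighted
    meta-analysis, the interaction-only effect-difference test, and their
    individual-level (mega-analysis) counterparts fitted with sex-specific
    residual variances by iterative feasible generalized least squares.
    Includes harmonization and quality control of per-sex summary-statistic
    files, numerically stable p-value machinery on the -log10 scale, a
    synthetic cohort and summary-statistic generator for type-I error and
    power studies, LD clumping with locus merging, and detection of variants
    with genome-wide significant effects in opposite directions between
    sexes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
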