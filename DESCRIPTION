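Package: scar16pls
Title: Genotype-Phenotype Modelling of SCAR16 from CHIP Mutant Biochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for spinocerebellar ataxia autosomal recessive 16
    (SCAR16) genotype-phenotype cohorts. Screens clinical and biochemical
    variables with Benjamini-Hochberg false-discovery control (Shapiro-Wilk and
    likelihood-ratio chi-square distribution tests, Fisher's exact test, pooled
    t tests, one-way ANOVA with Tukey-Kramer post hoc tests, simple
    regression), computes Pearson correlation screens and Ward minimum-variance
    clustering of standardized biochemical properties of mutant CHIP proteins,
    fits single- and multi-response partial least squares (NIPALS) models with
    leave-one-out cross-validation and VIP-based variable reduction exported as
    raw-scale linear equations, and runs Monte Carlo desirability simulations
    that search for biochemical settings predicted to delay ataxia onset and
    lower SARA scores. Includes a synthetic cohort generator emulating the
    cohort's categorical frequencies and linear effect structure so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    ape,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mixOmics
Config/testthat/edition: 3
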