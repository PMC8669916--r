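Package: tacrodose
Title: Genotype-Guided Tacrolimus Starting-Dose Modelling for Renal
    Transplant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pharmacogenetic analysis of dose-adjusted tacrolimus trough
    concentrations (C0/D) in renal transplant recipients. Provides a cohort
    data model with additive genotype encoding for five CYP3A5, CYP3A4 and
    ABCB1 polymorphisms; allele-frequency, Hardy-Weinberg and pairwise
    linkage-disequilibrium summaries (two-locus EM haplotype estimation with
    D, D' and r-squared); genotype-phenotype association (ANOVA and t-tests
    on C0/D, odds ratios with Woolf confidence intervals for post-transplant
    outcomes); a multivariable linear model for day-6 C0/D that is inverted
    into an integer-rounded, CYP3A5-genotype-guided starting-dose equation;
    and a seedable synthetic-cohort generator calibrated to published
    summary statistics so that every pipeline stage can be validated without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
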