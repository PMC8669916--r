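# tacrodose

Pharmacogenetic modelling of tacrolimus exposure in renal transplant
recipients, and the inversion of that model into a genotype-guided
starting-dose rule.

Tacrolimus has a narrow therapeutic index, and the dose needed to reach a
target whole-blood trough concentration (C0, ng/ml) varies several-fold
between patients. Much of that variability is genetic: carriers of the
functional CYP3A5 \*1 allele (rs776746, "expressors") clear the drug faster
than \*3/\*3 homozygotes ("non-expressors") and need higher doses for the
same exposure. `tacrodose` implements, as a tested reusable pipeline, the
analysis that quantifies this: genotype encoding and cohort management,
population-genetic quality checks, genotype–phenotype association, a
multivariable regression for dose-adjusted trough concentration, and the
dosing equation that falls out of it — together with a calibrated
synthetic-cohort generator so that every stage can be validated without
patient-level data.

The central quantity is the dose-adjusted trough concentration

    C0/D = C0 / (daily dose / body weight)        [(ng/ml) / (mg/kg/day)]

and the central model is ordinary least squares on day-6 C0/D:

    C0/D = b0 + b_age·age + b_male·male + b_3A5·g(CYP3A5)
              + b_3435·g(C3435T) + b_2677·g(G2677T)
              + b_1G·g(CYP3A4*1G) + b_1B·g(CYP3A4*1B) + e

where each `g(·)` is an additive 0/1/2 variant-allele count; for CYP3A5,
`g` counts \*1 alleles, so `g = 0` is the non-expressor genotype. Rounding
the fitted constant (158.74) and CYP3A5 coefficient (−40.48) to integers
inverts the model into a bedside rule for the starting dose:

    required dose (mg/kg/day) = desired day-6 C0 / (159 − 40·g)

Supporting machinery includes Hardy–Weinberg chi-square tests, two-locus EM
haplotype estimation with D, D′ and r² (CYP3A5\*3 and CYP3A4\*1G sit 
close together on 7q21.1 and are in strong LD, D′ ≈ 0.92), and 2×2
odds-ratio analysis with Woolf confidence intervals for post-transplant
outcomes (NODAT, rejection, toxicity) by expressor status.

## Worked example

Simulate a large cohort from the regression-calibrated generator, apply the
association-analysis exclusions, refit the C0/D model and derive a dosing
equation:

```r
library(tacrodose)

cohort <- generate_cohort(default_study_config(n_patients = 2000, seed = 42,
                                               c0d_model = "regression"))
cohort <- filter_for_association(cohort)
#> filter_for_association: removed 451/2000 patients
#>   (227 delayed graft function, 249 early graft dysfunction)

fit <- fit_c0d_model(cohort)
fit
#> Linear model for day6 C0/D (n = 1421)
#>   term        estimate std_error  ci_low ci_high   p_value
#>   (Intercept)  163.        7.09  149.    177.    6.47e-100
#>   age           -0.502     0.135  -0.766  -0.238 2.02e-  4
#>   male           6.76      3.50   -0.118  13.6   5.40e-  2
#>   rs776746     -41.1       3.14  -47.3   -35.0   3.83e- 37
#>   rs1045642    -14.0       1.95  -17.8   -10.2   1.03e- 12
#>   rs2032582     11.5       1.93    7.68   15.2   3.37e-  9
#>   rs2242480    -12.3       2.97  -18.2    -6.50  3.52e-  5
#>   rs2740574    -10.8       4.06  -18.8    -2.88  7.62e-  3
#>   R-squared = 0.353
```

The fitted coefficients recover the generative model (constant 158.74,
CYP3A5 −40.48 per \*1 allele, R² = 0.353): CYP3A5 genotype is the dominant
predictor, each \*1 allele lowering C0/D by about 41 (ng/ml)/(mg/kg) —
expressors need proportionally more drug.

```r
derive_dosing_equation(fit)
#> required dose (mg/kg/day) = desired day-6 C0 / (163 - 41 x CYP3A5 *1-allele count)

eq <- dosing_equation(158.74, -40.48)   # the published coefficient table
round(required_dose_per_kg(eq, desired_c0 = 8.5, genotype_code = 0:2), 4)
#> [1] 0.0535 0.0714 0.1076
```

A \*1/\*1 expressor targeting a day-6 trough of 8.5 ng/ml needs roughly
twice the weight-adjusted dose of a \*3/\*3 non-expressor. Outcome tables
work from counts directly:

```r
two_by_two(39, 30, 28, 48)   # NODAT by expressor status (rows: non-expressor)
#> OR = 2.229 (95% Woolf CI 1.145-4.338)
#> Pearson chi2 = 5.635, p = 0.01761
```

Non-expressors — who run higher troughs at the same dose — carry about
2.2-fold higher odds of new-onset diabetes after transplantation.

`run_pipeline(pipeline_config(...))` sequences all of the above and writes
a publication-style report bundle (SNP summary, LD table, association
tables, regression, dosing equation, run log); a thin command-line wrapper
with `simulate`/`summarize`/`ld`/`associate`/`fit`/`dose`/`run-all`
subcommands ships in `inst/cli/tacrodose.R`. A 12-patient synthetic example
file conforming to the cohort CSV schema is at
`system.file("extdata", "example_cohort.csv", package = "tacrodose")`.

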