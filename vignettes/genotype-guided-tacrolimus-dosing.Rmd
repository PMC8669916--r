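---
title: "Genotype-guided tacrolimus dosing: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-guided tacrolimus dosing: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacrodose)
```

## The problem

Tacrolimus keeps a transplanted kidney from being rejected, but only inside
a narrow window of whole-blood trough concentration (C0): too little risks
rejection, too much risks nephrotoxicity and new-onset diabetes (NODAT).
Dosing is conventionally weight-based and then corrected by therapeutic
drug monitoring — which can only react *after* the patient has been exposed.
A large share of the between-patient variability is genetic. The CYP3A5
enzyme is only produced by carriers of the functional \*1 allele at
rs776746; \*3/\*3 homozygotes ("non-expressors") clear the drug slowly and
run high troughs at standard doses, while expressors need substantially
more drug. `tacrodose` packages the statistical pipeline that quantifies
these effects in a renal-transplant cohort and turns the fitted model into
a pre-transplant starting-dose rule.

The exposure measure throughout is the dose-adjusted trough

$$ C_0/D \;=\; \frac{C_0\ (\mathrm{ng/ml})}{\text{daily dose (mg)} / \text{weight (kg)}}, $$

in (ng/ml)/(mg/kg/day): the trough the patient would show per unit of
weight-adjusted dose. High C0/D means slow clearance.

## Cohort model and exclusions

A cohort is a validated patient table plus the five-SNP panel
(`snp_definitions()`): CYP3A5\*3 (rs776746), CYP3A4\*1G (rs2242480),
CYP3A4\*1B (rs2740574), ABCB1 G2677T (rs2032582) and ABCB1 C3435T
(rs1045642). Genotypes are unordered allele pairs; encoding is additive —
`encode_genotypes()` counts copies of each SNP's *coded* allele. For CYP3A5
the coded allele is \*1, so the code is 0/1/2 for \*3/\*3, \*1/\*3, \*1/\*1,
which is exactly the genotype variable of the dosing equation. For the
other four SNPs no published coding is stated; we adopt the additive count
of the named variant allele (\*1G, the \*1B promoter G, and the two ABCB1 T
alleles), configurable per SNP definition. Additive coding is the only
scheme consistent with a single regression coefficient per SNP.

Patients with delayed graft function or early graft dysfunction in the
first post-transplant week are excluded from all C0/D analyses
(`filter_for_association()`), because their management (dialysis, dose
interruptions) distorts tacrolimus levels. Missing data are handled by
listwise deletion per analysis: a patient missing one genotype is dropped
only from analyses that use that SNP, which is why each summary table
carries its own n. No imputation is performed.

## Population-genetic checks

`hwe_test()` compares observed genotype counts with Hardy–Weinberg
expectations ($np^2, 2npq, nq^2$) by Pearson chi-square on one degree of
freedom, without continuity correction — matching the spreadsheet-style
calculators typically used for this check. Monomorphic loci are flagged
rather than tested.

`em_haplotypes()` estimates two-locus haplotype frequencies from unphased
genotypes. Every genotype pair except the double heterozygote determines
its haplotypes; the double heterozygote is a mixture of AB/ab and Ab/aB
phases, which the EM resolves by iterating between (E) splitting the
double-het count in proportion to the current haplotype-product weights and
(M) re-estimating the four frequencies from expected haplotype counts.
Numerical choices: initialisation at linkage equilibrium (products of the
sample allele frequencies), convergence when no frequency moves more than
`tol = 1e-10` (iteration cap 1000, both configurable), and an internal
assertion that the log-likelihood never decreases. Because allele counts
are fixed by the data, the estimated haplotype margins equal the sample
allele frequencies at every iteration. From the converged frequencies we
report $D = f_{AB} - p_A p_B$, Lewontin's $D' = |D|/D_{\max}$ and
$r^2 = D^2 / (p_A q_A p_B q_B)$. The test suite checks the EM against a
brute-force grid search over the one free haplotype frequency: with margins
fixed, the likelihood has a single free parameter, so a fine grid is a
complete independent oracle.

CYP3A5\*3 and CYP3A4\*1G lie close together on 7q21.1 and are in strong LD
($D' \approx 0.92$, $r^2 \approx 0.64$ at the calibrated frequencies). This
matters for interpretation: in univariate analysis both SNPs associate
strongly with C0/D, but in the joint regression the CYP3A4\*1G term is
largely absorbed by CYP3A5 — and at n ≈ 100 the two collinear coefficients
are individually unstable even though their sum is well determined. The
package reports all ten SNP pairs, not just this one.

## Association analyses

`group_c0d()` summarises C0/D per genotype group and tests the difference:
one-way ANOVA for three genotype groups, a two-sided independent-samples
t-test for two (equal variances by default, matching the SPSS-era reporting
convention; Welch via `welch = TRUE`). Groups with fewer than two
observations are excluded from the test and flagged.

`two_by_two()` analyses outcome-by-exposure tables: odds ratio
$(ad)/(bc)$, 95% Woolf interval
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$, and a Pearson
chi-square without continuity correction. The Yates correction is available
(`correct = TRUE`) but off by default: on the NODAT table the uncorrected
chi-square gives p ≈ 0.018 and the corrected one ≈ 0.027, and only the
uncorrected value reproduces the published figure. Zero cells trigger the
Haldane–Anscombe +0.5 correction for the OR and interval, with a flag. No
multiple-testing correction is applied; raw p-values are reported and the
pipeline log records how many tests were run.

Expressor status (carrier of ≥ 1 \*1 allele vs \*3/\*3) is the exposure for
the outcome tables. The at-risk orientation differs by outcome —
non-expressors for NODAT and toxicity, expressors for rejection — so
`two_by_two_outcome()` takes the exposed group explicitly.

## The dose model and its inversion

`fit_c0d_model()` fits OLS of day-6 C0/D on a constant, age, male sex and
the five additive genotype codes, on complete cases, with classical
standard errors and Student-t confidence intervals on n − k degrees of
freedom. Covariates that are constant in the analysis sample are dropped
with a warning (relevant for the rare CYP3A4\*1B variant in small cohorts);
collinear designs are an error naming the offending terms.

`derive_dosing_equation()` rounds the fitted constant and CYP3A5
coefficient to integers — half away from zero, the rule that maps 158.74 to
159 and 40.48 to 40 simultaneously (truncation would not) — and asserts
that the denominator $159 - 40g$ stays positive at every genotype code.
`required_dose_per_kg()` then inverts the model: dose per kg equals the
desired day-6 trough divided by the genotype-specific denominator. The dose
is nondecreasing in the \*1-allele count and linear in the target level.
Only the day-6 fit is turned into an equation; fits at month 6 and year 1
can be reported but describe maintenance-phase exposure, not the starting
dose. No clamping is applied to the computed dose; the command-line
interface warns when it falls outside the 0.075–0.1 mg/kg/day institutional
starting range or above the 0.3 mg/kg/day consensus cap.

A rounding note: dosing a hypothetical noise-free model-mean patient by the
rounded equation returns the target trough to within 0.2% at code 0 and
1.6% at code 2 (the exact ratios $(158.74 - 40.48g)/(159 - 40g)$); the
integer rule trades that small bias for bedside usability.

## The synthetic-cohort generator

`generate_cohort()` exists so that every stage has a test bed with known
truth. Its defaults (`default_study_config()`) are fixed to the study
conditions:

* n = 145 patients; age ~ Normal(36.61, 10.58) truncated to the 15–60-year
  inclusion window; 81.4% male; day-6 weight ~ Normal(59.55, 12.82) kg
  truncated positive (62.98 and 63.63 at month 6 / year 1).
* The linked rs776746–rs2242480 pair is drawn as two haplotypes per patient
  from frequencies solved by `ld_hap_freqs(0.314, 0.380, 0.922)` — the
  observed coded-allele frequencies and D′. Random union of gametes makes
  single-SNP genotypes Hardy–Weinberg-consistent by construction, and the
  implied $r^2 = 0.635$ agrees with the observed 0.64, confirming the
  calibration is internally coherent. The other three SNPs are independent
  binomial draws at their observed frequencies (0.053, 0.641, 0.646).
* Small per-SNP missingness probabilities reproduce the observed per-SNP n
  (145, 142, 141, 142, 144).
* Day-6 C0/D comes from one of two models. The default **group model**
  draws from Normal components per CYP3A5 genotype — mean (SD) 145.45
  (54.99), 77.10 (38.43), 66.46 (36.09) for codes 0/1/2 — reproducing the
  published group summaries directly; month-6 and year-1 values draw from
  the corresponding printed group parameters, with availability
  probabilities 89/145 and 66/145. The **regression model**
  (`c0d_model = "regression"`) instead generates day-6 C0/D from the
  published coefficients with residual sd
  $60.42\sqrt{1 - 0.353} = 48.6$ — the marginal C0/D sd deflated by the
  model's R² — and is the configuration used for parameter-recovery
  checks.
* The (dose, C0) pair is back-solved: weight-adjusted dose uniform on the
  0.05–0.08 mg/kg/day protocol range, then $C_0 = (C_0/D) \times
  \text{dose/kg}$, so the C0/D identity holds exactly by construction.
* Outcomes are Bernoulli with expressor-dependent probabilities taken from
  the published 2×2 tables (NODAT 39/69 vs 28/76, rejection 11/69 vs 24/76,
  toxicity 22/68 vs 18/75); delayed graft function at 11% and early graft
  dysfunction at 13.1%, independent of genotype.

Deliberate unrealisms, and what passing tests therefore do and do not show:
the Normal residual is not truncated at zero, so roughly 1–2% of simulated
C0/D values (mostly expressors) are negative — truncation would bias the
calibrated group means and attenuate regression recovery, and we prioritise
exact calibration over physiological plausibility in the tail. Outcomes are
generated independently given expressor status (their real correlation is
unreported); there is no dose-titration feedback over the year, so
month-6/year-1 values are marginal draws, not trajectories; and genotype
missingness is completely at random. Tests on this generator validate the
*estimators* and the *pipeline plumbing* under the study's statistical
structure — they cannot validate clinical transportability of the dosing
equation, which requires a prospective cohort.

## Problem sizes used in validation

The test suite and acceptance script size their simulations as follows:
parameter recovery uses 500 cohorts of n = 92 (the day-6 complete-case
count implied by the genotype-group sums), which bounds the Monte-Carlo
standard error of the mean CYP3A5 coefficient near 0.7; generator-closure
checks use a single n = 20,000 cohort, where binomial error puts allele
frequencies within ±0.005 and the stratum means within ±1; the EM oracle
uses 20-patient tables where brute-force grid search is exact enough at a
$10^{-4}$ step. These sizes were chosen so every check is decisive at its
stated tolerance while the whole suite runs in about a minute.

## Known limitations

The dosing equation is population-specific: allele frequencies of CYP3A5,
CYP3A4 and ABCB1 variants differ markedly between world populations, so the
integer constants should be re-derived, not transplanted, for a new
population. The regression is cross-sectional at day 6 and does not model
within-patient pharmacokinetics; hemoglobin, drug–drug interactions and
food effects are outside the covariate set. The equal-variance t-test and
uncorrected chi-square defaults are fidelity choices, not statistical
recommendations; both have toggles. Finally, the EM implementation is
strictly two-locus — multi-SNP phasing is out of scope.
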