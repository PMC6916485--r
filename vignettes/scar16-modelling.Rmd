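---
title: "Modelling the SCAR16 disease spectrum from CHIP biochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the SCAR16 disease spectrum from CHIP biochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scar16pls)
```

## The problem

SCAR16 is a recessive cerebellar ataxia caused by coding mutations in
*STUB1*, the gene for the ubiquitin ligase/cochaperone CHIP. Patients differ
widely in age of onset (AOO), ataxia severity (SARA, a 0–40 scale),
cognitive dysfunction (CD), tendon reflexes (TR) and hypogonadism, and the
mutations scatter across CHIP's three domains (TPR, coiled-coil, Ubox) with
very different biochemical consequences: binding affinity (K~D~) and
capacity (B~max~) for the HSP70 EEVD motif, HSP70 ubiquitination,
E2-dependent ubiquitin-chain formation, thermostability, oligomerization
and cellular stability. The analytical question this package operationalizes
is: *which changes in CHIP biochemistry track which clinical phenotypes, and
what combination of biochemical changes would predict milder disease?*

The pipeline has four statistical layers — univariate distribution tests,
bivariate association screens under FDR control, multivariate correlation
and clustering structure, and reduced PLS models feeding a Monte Carlo
desirability search. Each layer is exposed as ordinary functions over plain
tables, and `run_pipeline()` chains them.

## Data model and per-allele analysis

Patient records carry sex, ancestry super-population (AMR/SAS/MENA/EUR/EAS),
homozygosity, two allele labels, AOO (> 0 years), SARA (clamped to the scale
bounds [0, 40]) and the Y/N phenotypes. Validation is strict: unknown
categorical levels and out-of-range values are load errors naming the row
and field, because silent coercion in a 24-row cohort can flip a conclusion.
Missing values are tolerated only where the cohort itself is incomplete
(AOO, hypogonadism); every test then drops incomplete rows for its own
variables, so per-test n varies exactly as a complete-case analysis implies.

Biochemistry attaches to alleles, not patients. `explode_alleles()` expands
each patient into one record per substitution mutation, excluding
preterminal stop codons and frameshifts (recognized by pattern:
`K144*`, `Y230Cfs*8`, …) whose transcripts are expected to undergo
nonsense-mediated decay and were never characterized at the protein level.
Whether a homozygote counts its mutation once or twice is a genuine
ambiguity in per-allele summaries, so the copy policy is a configuration
switch: `per_allele_copy` (default; copies = 2) or `per_distinct_mutation`.
The mutation→domain map ships as a versioned resource file
(`extdata/chip_domain_map.csv`) rather than hard-coded logic; the bundled
map assigns the 13 characterized substitutions by CHIP residue range
(TPR ≤ 127, CC 128–226, Ubox ≥ 227) and users may substitute their own.

## Screening choices

* **Distribution tests.** Continuous variables use Shapiro–Wilk; categorical
  variables use the likelihood-ratio χ² against an equal-frequency null over
  the *observed* levels (df = k − 1). The equal-frequency null over observed
  levels is an interpretation choice — nothing in a cohort table defines the
  reference level set — and it reproduces the published cohort p-values
  (11/13 split → 0.6829; 4/20 → 0.0006).
* **t tests** default to pooled variance, since the source analyses say
  "t test" without a Welch qualification; Welch is available via
  `welch = TRUE`. Group levels are ordered lexicographically so results are
  invariant to row order and relabeling only flips the sign.
* **Fisher's exact test** uses the two-tailed point-probability definition
  (sum the probabilities of all margin-fixed tables no likelier than the
  observed), which is what `fisher.test()` implements and what the tests
  verify against an exhaustive hypergeometric enumeration. A zero margin is
  reported as p = 1 with a `degenerate` flag rather than an error: a table
  with an empty row carries no evidence about association, and a screening
  loop should not die on it.
* **ANOVA post hoc** comparisons use Tukey–Kramer, valid for the unbalanced
  groups a natural cohort produces; singleton levels are excluded (they
  contribute no within-group variance) and reported.
* **Multiplicity.** Q values are Benjamini–Hochberg, adjusted within one
  family per screen (one response against its predictor set, or one
  correlation matrix's upper triangle) — mirroring per-analysis adjustment
  rather than one global family. Flags use Q < 0.10. Note that the step-up
  transform is not idempotent: re-adjusting an already adjusted family can
  only raise values (constant families are fixed points), so Q values are
  computed once, from raw p-values.

## Correlations and clustering

Correlations are pairwise-complete Pearson ρ with p from the t transform.
Pairwise (not listwise) deletion is deliberate: K~D~ happens to be complete
in the reference biochemistry table, but user tables often are not, and a
single missing cell should not shrink every other pair's n. Zero-variance
variables yield missing entries, not errors.

`ward_cluster()` standardizes variables to sample SD 1 (so clustering is
invariant to units) and applies Ward's minimum-variance linkage. The linkage
is delegated to `hclust(method = "ward.D2")`, whose heights h relate to the
error-sum-of-squares increase of each merge as ESS = h²/2; the object
exposes both, and the tests verify the ESS increments against a brute-force
greedy agglomeration on small instances. Merge ties are broken by `hclust`'s
deterministic ordering of the distance vector; with continuous standardized
data exact ties essentially never arise.

## The PLS engine

Design encoding standardizes continuous predictors and effect-codes
categorical ones. The default coding keeps one indicator column per level
("full"), because the exported equations report an offset for *every* level
(e.g. ±5.6 for CD yes/no, five ancestry offsets); a k−1 sum-contrast coding
("sum") is available. All coded columns are autoscaled, which is what makes
VIP comparable across mixed predictor types.

Fitting is classical multi-response NIPALS with deflation of both blocks
(tolerance 1e−10, ≤ 500 inner iterations, non-convergence is an error naming
the factor). Responses are centered and scaled during fitting and equations
are exported back to the raw response scale, because years of onset and SARA
points are the units in which the models are read. With as many factors as
the rank of a full-rank design, predictions provably coincide with OLS, and
the suite asserts this on random instances as well as against an independent
PLS implementation.

Factor count is chosen by leave-one-out cross-validation: PRESS is
accumulated on the standardized response scale with both blocks re-centered
and re-scaled inside every fold (no leakage), and the *first local minimum*
of PRESS is selected, with improvements below 10⁻⁶ of the intercept-only
PRESS counted as flat so that numerically-zero curves do not inflate the
factor count. A = 0 (intercept only) is a legitimate selection for pure
noise. Reduction is one-pass: fit everything, drop coded columns with
VIP ≤ 0.8 (a factor stays if any of its level columns clears the cutoff),
refit once with at most the initial factor count. The exported
`linear_equation` centers each factor's offsets to sum to zero exactly,
absorbing the shift into the intercept, which leaves predictions unchanged;
published equations with rounded coefficients are accepted with an offset
tolerance of one rounding unit (one reference model's ancestry offsets sum
to −0.9, presumably from printing precision).

## The desirability profiler

`run_simulation()` draws every biochemical input from
normal(setting, SD) — the SDs being the cohort scales printed in the
equations (15.5, 39.0, 6.0, 16.6) — and pushes each draw through the affine
response equations, so the analytic response mean at the baseline settings
equals the intercept (20.6 years, 18.8 points); Monte Carlo means converge
at 1/√n, which the tests check at three draw counts.

Desirability uses one-sided linear Derringer–Suich ramps: for "maximize",
0 at the target's reflection about the anchor, 0.5 at the anchor (the
baseline mean), 1 at the target and beyond; "minimize" mirrors this. The
functional form is a design choice — the methodology names desirability
maximization but not the curve — so a smoothstep variant is selectable
(`curve = "smooth"`). Targets sit one *cohort* response SD from the
baseline mean: +11 years AOO and −10 SARA points. The cohort SDs, not the
model SDs, are the right scale here: the reduced SARA-from-biochemistry
model has a model SD near 3 points, and a 3-point target would declare
victory long before a clinically meaningful improvement. Overall D is the
geometric mean of the per-response mean desirabilities, so a setting that
helps one response while zeroing the other scores 0.

`optimize_settings()` searches over input *means* only (the SDs are
properties of the assay spread, not knobs), within mean ± 3 SD bounds
floored at 0 for these physically nonnegative quantities. The search is a
seeded Latin-hypercube start plus two passes of coordinate refinement, all
candidates scored on a common-random-number draw set sized so the total
draw budget (default 5000) is respected; the common draws make the
objective deterministic, so coordinate refinement is meaningful. The
returned optimum is re-simulated at full size and compared against the
baseline simulated the same way; the baseline is returned if it scores at
least as well, making "never worse than baseline" a structural guarantee.
With the reference equations the optimum lands where expected: HSP70
ubiquitination and chain formation driven down, K~D~ up — i.e. further
inhibition of mutant CHIP's activity toward HSP70 predicts later onset and
milder ataxia.

## The synthetic generator

`generate_cohort()` exists so every downstream stage has data with *known*
ground truth. It emulates: the cohort's categorical frequencies (46%
homozygous, 75% TR, 17% hypogonadism, the 4/4/25/34/33 ancestry mix), the
biochemical input locations/scales, the conditional CD rates (94% given a
Ubox allele, 59% otherwise — the allele-level Ubox probability of 0.31 is
back-calculated so the implied CD prevalence is the cohort's 71%), a
homozygosity offset of ∓6 years on AOO (the 12-year onset gap), and the
linear effect structures themselves: SARA from the clinical equation, AOO
from the biochemical equation, plus Gaussian residuals. The residual SDs
are free parameters (the source models report none): SARA 7 — consistent
with a model explaining ~54% of a variance of ~100 — and AOO 5.

Deliberate non-goals: the generator does not reproduce mutation-spelling
realism, linkage between domain and oligomerization, correlation among the
biochemical inputs (each mutant's properties are drawn independently), or
the exact AOO/SARA marginal medians — responses come from the effect
models, because parameter-recovery tests need structure, not distributional
cosmetics. Physical bounds are enforced by truncation (clamping), not
resampling; this slightly biases means upward when SD/mean is large (K~D~'s
truncated mean is ~8.9 against a nominal 7.8 — visible only through the
wide 13-mutant sampling error). Consequently, passing tests demonstrate
that the machinery recovers known structure at cohort-like scales; they do
not demonstrate that real SCAR16 data satisfy the models' assumptions.

## Numerical and testing notes

Problem sizes in the test suite are chosen for a laptop-scale run: OLS
equivalence on n ≤ 50, p ≤ 6; Ward-vs-brute-force on n ≤ 8; exhaustive
Fisher enumeration over all nondegenerate 2×2 tables with total ≤ 40;
coefficient recovery at n = 500 over 20 seeds (±15% tolerance, ≥ 80%
coverage); screening type-I error over 500 null replicates at n = 24.
Degenerate inputs are first-class: constant predictors and single-level
factors are errors at encoding, zero-variance variables are missing
correlations, zero-margin tables are flagged p = 1, all-identical samples
are distribution-test errors, and zero input SDs collapse the simulation to
the affine evaluation.

Known limitations: one-pass (not iterative) VIP reduction; no sparse or
regularized PLS and no bootstrap intervals on coefficients; desirability
weights are equal across responses; the optimizer is a bounded heuristic
search, appropriate for smooth affine objectives but not a global optimizer
for arbitrary response surfaces; and reproducing the published coefficient
decimals from patient-level data depends on the original software's
categorical scaling conventions, so sign and ranking — not printed
decimals — are the contract for refits.
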