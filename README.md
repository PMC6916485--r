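# scar16pls

Genotype–phenotype modelling for **SCAR16** (spinocerebellar ataxia autosomal
recessive 16), the ataxia caused by coding mutations in *STUB1*/CHIP — a
ubiquitin ligase and HSP70 cochaperone with TPR, coiled-coil and Ubox
domains. The package is aimed at rare-disease statisticians and protein
biochemists who want to relate the clinical spectrum of a small cohort
(age of onset AOO, SARA ataxia score, cognitive dysfunction CD, increased
tendon reflex TR, hypogonadism) to the biochemical repercussions of each
substitution mutation (K_D and B_max of the CHIP–HSP70 EEVD interaction,
%HSP70 ubiquitination, %ubiquitin-chain formation, T_m, oligomeric state,
cellular stability).

It provides, end to end:

* a **typed data model** for the patient and biochemistry tables with
  validated CSV readers and per-allele expansion (stop-codon alleles
  excluded, homozygotes counted per allele copy or per distinct mutation);
* **screening statistics** — Shapiro–Wilk and likelihood-ratio χ²
  distribution tests, two-tailed Fisher's exact tests, pooled t tests,
  one-way ANOVA with Tukey–Kramer post hoc comparisons, simple regression —
  with Benjamini–Hochberg Q values per screening family (FDR < 10% flags);
* **multivariate structure** — pairwise-complete Pearson correlation screens
  and Ward minimum-variance clustering of standardized biochemical
  variables, exported as long tables and Newick trees;
* a **PLS engine** (multi-response NIPALS) with effect-coded categorical
  predictors, leave-one-out PRESS factor selection, VIP computation
  (`VIP_j = sqrt(p · Σ_a SS_a w_ja² / Σ_a SS_a)`), one-pass reduction at
  VIP > 0.8, and export of the reduced model as a raw-scale linear equation;
* a **Monte Carlo desirability profiler** that draws the biochemical inputs
  from normal distributions, scores each response with one-sided
  Derringer–Suich ramps (overall desirability D = geometric mean), and
  searches input settings for biochemistry predicted to delay onset and
  lower SARA;
* a **synthetic cohort generator** whose defaults encode the cohort's
  categorical frequencies and the reduced models' effect structure, so that
  every stage is testable without patient-level data.

The central models are the reduced PLS equations, e.g. for age of onset as a
function of mutant CHIP biochemistry:

```
AOO_adj = 20.6 − 3.9[(%HSP70ub − 43.7)/15.5] + 5.3[(%Chain − 69.9)/39.0]
               + 4.9[(K_D − 7.8)/6.0] − 7.1[(B_max − 212.0)/16.6]
```

with the companion SARA equation (intercept 18.8, coefficients +1.9, +0.2,
−2.3, +0.3 on the same standardized inputs). `scar16_reference_equations()`
ships all three published reduced models (the clinical SARA model with its
±5.6 CD, ancestry and ±2.7 TR offsets, and both biochemical models).

## Worked example

```r
library(scar16pls)

spec <- scar16_simulation_spec(seed = 7)   # AOO/SARA models, 5000 draws
run_simulation(spec)                       # baseline biochemistry
#> <sim_result> 5000 draws, D = 0.5037
#>   aoo: mean 20.76 (sd 11.13), desirability 0.505
#>   sara: mean 18.75 (sd 3.03), desirability 0.503

opt <- optimize_settings(spec)             # search for better biochemistry
round(opt$settings, 1)
#> pct_hsp70_ub    pct_chain           kd         bmax
#>          0.0         31.2         25.8        162.2
opt$result
#> <sim_result> 5000 draws, D = 0.9948
#>   aoo: mean 62.49 (sd 11.13), desirability 0.999
#>   sara: mean 5.39 (sd 3.03), desirability 0.990
```

The baseline run reproduces the cohort-level expectations (mean AOO ≈ 20.6
years, mean SARA ≈ 18.8 within Monte Carlo error; the affine models make the
exact means equal the intercepts). The optimizer pushes the biochemistry in
the direction that lessens predicted disease — less HSP70 ubiquitination,
less chain formation, weaker HSP70 binding (higher K_D) — and never returns
settings scoring below baseline desirability. Screening works the same way
on any cohort table:

```r
gen <- generate_cohort(generator_params(n_patients = 24, seed = 7))
screen(transform(gen$cohort, homozygous = ifelse(homozygous, "Y", "N")),
       "sara", c("cd", "tr", "sex"))
#>   test_name x_var statistic      p     q flagged
#> 1 pooled_t  cd       -0.155 0.878  0.878 FALSE
#> 2 pooled_t  tr       -0.821 0.420  0.631 FALSE
#> 3 pooled_t  sex       2.13  0.0444 0.133 FALSE
```

(a 24-patient synthetic cohort is too small to flag its generating effects
at FDR < 10% — by design the generator mimics the cohort's power, not an
idealized one). `run_pipeline(run_config(out_dir = "out", seed = 1))` runs
every stage and writes the distribution, contingency, screening,
correlation, PLS, simulation and contour-grid tables plus a checksummed
manifest.

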