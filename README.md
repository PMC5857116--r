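# starmh

Derivation and validation toolkit for the **STAR-MH**, a brief screen for
major depressive disorder (MDD) and post-traumatic stress disorder (PTSD) in
asylum-seekers and refugees. The fielded instrument consists of two
*immediate screen-in* items (a positive answer ends the screen as positive)
followed by a 7-item dichotomous scale summed against a cut-score (≥2 as
fielded). The package is written for psychometricians and screening-tool
developers who want to rerun — or adapt to a new item bank — the full
validation workflow behind such an instrument:

- **Item selection**: per-item sensitivity/specificity and Cohen's-kappa
  filters against interview caseness, Spearman-correlation and
  predictive-accuracy floors, CART retention, and endorsement-specificity
  curves (the probability of endorsing an item when endorsing nothing else,
  used to drop low-specificity items).
- **Rasch measurement**: conditional maximum likelihood (CML) estimation of
  the dichotomous Rasch model
  `P(X_vi = 1) = exp(θ_v − β_i) / (1 + exp(θ_v − β_i))`
  via log-domain elementary symmetric functions and Newton iterations;
  sum-zero difficulties with standard errors; ML person abilities; infit and
  outfit mean squares with Wilson–Hilferty standardized fit statistics and
  Bonferroni-adjusted chi-square tests; person separation index (PSI) and
  mean inter-item correlation.
- **Structure**: unidimensionality by modified parallel analysis on the
  second eigenvalue of the inter-item tetrachoric matrix, with a Monte Carlo
  null drawn conditionally on each person's raw score; local dependence by
  Ponocny's T1 quasi-exact test over margin-fixed matrices sampled with a
  compiled checkerboard-swap chain.
- **DIF**: logistic-regression differential item functioning (joint uniform
  and non-uniform, 2 df) with Nagelkerke ΔR² effect sizes
  (negligible < 0.035 ≤ moderate ≤ 0.07 < large) and Benjamini–Hochberg
  control within each grouping family.
- **Diagnostic accuracy**: ROC curve, Mann–Whitney AUC with DeLong 95% CI,
  Harrell bootstrap optimism correction, per-cutoff tables
  (SN/SP/PLR/NLR/PPV/NPV/efficiency with Clopper–Pearson and log-method CIs)
  and Youden cut-score selection.
- **Synthetic cohorts**: a Rasch-based generator reproducing the validation
  study's geometry (the raw responses were never deposited), with optional
  injected DIF, a second factor, and MCAR missingness.

The published summary tables of the original validation study (recruitment
counts, endorsement frequencies, item difficulties, per-cutoff SN/SP) ship
as data constructors (`starmh_recruitment()`, `starmh_endorsement_counts()`,
`starmh_difficulties()`, `starmh_published_cutoffs()`) and anchor both the
generator and the reproduction checks.

## Worked example

```r
library(starmh)

sim <- simulate_cohort(sim_config(seed = 42))     # 185 persons, 33% prevalence
items <- starmh_difficulties()$item
m <- sim$cohort$responses[, items]

fit <- fit_cml(m)
print(fit)
#> Rasch CML fit: 7 items, 105 non-extreme persons, logLik -280.96 (converged in 4 iterations)
#>           difficulty    se
#> restless      -0.020 0.197
#> interest       0.072 0.199
#> crazy          0.357 0.204
#> fearful        0.308 0.203
#> trapped       -0.499 0.193
#> pain          -0.198 0.195
#> worthless     -0.020 0.197

reliability(fit, m)$psi
#> [1] 0.72

scores <- rowSums(m)
auc_with_ci(scores, sim$cohort$caseness)
#> $auc 0.914   $ci 0.873 0.955

youden_select(cutoff_table(scores, sim$cohort$caseness, 1:7), sn_floor = 0.90)
#> $optimal_cutoff 2   $sensitivity_privileged_cutoff 2
```

The difficulties recover the generating (published) values within their
standard errors; the PSI, AUC and cut-score behaviour match the validation
study's findings (PSI 0.75, AUC 0.912, optimal cut-score 3 with ≥2 preferred
for sensitivity — at n = 185 the Youden optimum fluctuates between 2 and 3
across cohorts, exactly the instability the study discusses).

The end-to-end run is one call:

```r
rep <- run_validation_report(sim$cohort, validation_config(), seed = 1,
                             out_dir = "results/report")
```

## Analysis workflow

The numbered scripts under `analysis/` are thin narrative drivers over the
package and write their tables under `results/`:

| script | stage |
| --- | --- |
| `00_tune_generator.R` | one-off calibration grid behind the generator defaults |
| `01_simulate_cohort.R` | generate and write the working cohort CSV |
| `02_derivation_cascade.R` | item-selection cascade on an item bank with noise items |
| `03_scoring_accounting.R` | fielded scoring, endorsement and participation arithmetic |
| `04_rasch_structure.R` | CML fit, item fit, reliability, parallel analysis, T1 |
| `05_dif.R` | DIF screen across the eight grouping covariates |
| `06_diagnostics.R` | ROC, optimism correction, cutoff table, cut-score selection |
| `07_full_report.R` | the single-call validation report |

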