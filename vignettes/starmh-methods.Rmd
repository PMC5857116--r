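---
title: "Methods behind the STAR-MH validation workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the STAR-MH validation workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmh)
```

## The instrument and the measurement model

The STAR-MH screens adult asylum-seekers and refugees for major depressive
disorder and post-traumatic stress disorder against a structured-interview
reference diagnosis ("caseness" = MDD and/or PTSD). It has two *immediate
screen-in* items — a positive answer classifies the person screen-positive
and ends the screen — followed by a 7-item dichotomous scale whose sum is
compared with a cut-score (≥2 as fielded). `score_star_mh()` and
`classify_cohort()` implement exactly this decision logic; with
`early_exit = FALSE` the outcome is invariant to item order, and positivity
is monotone non-increasing in the cut-score.

Scale measurement uses the dichotomous Rasch model: the probability of
endorsing item $i$ is a logistic function of person ability $\theta_v$
(here: psychological distress, in logits) minus item difficulty $\beta_i$,

$$P(X_{vi}=1\mid\theta_v,\beta_i)=\frac{e^{\theta_v-\beta_i}}{1+e^{\theta_v-\beta_i}}.$$

The model assumes a single latent dimension, equal item discrimination, and
local independence given $\theta$; the structure module tests the first and
third assumptions, and item fit statistics the second.

## Conditional maximum likelihood

`fit_cml()` estimates difficulties by conditioning on the raw-score margins,
which eliminates the person parameters: the conditional likelihood factors
through the elementary symmetric functions (ESFs) $\gamma_r(\varepsilon)$ of
the easiness parameters $\varepsilon_i=e^{-\beta_i}$. Numerical choices:

- ESFs by the summation recursion in the log domain (`log_esf`), so the
  computation is stable for any difficulty spread; tests verify it against
  brute-force enumeration of all $2^m$ patterns up to $m=10$.
- Newton iterations with the analytic gradient (observed minus conditionally
  expected item margins) and Hessian (the summed conditional covariance of
  the item indicators given raw score); convergence when the gradient
  infinity-norm falls below `1e-8`. Four to six iterations are typical.
- Identification by fixing the first difficulty during iteration, then
  shifting to the **sum-zero convention** for reporting; standard errors come
  from the inverse conditional information via the delta method. The
  sum-zero convention is why the published difficulty column sums to 0.01
  (rounding residue of seven values printed to two decimals).
- Persons with zero or perfect raw scores carry no conditional information
  and are excluded from estimation and item fit; items that are constant
  among the remaining persons raise an *inestimable item* error naming the
  item.

ML abilities solve $\sum_i P(\theta,\beta_i)=r$ per raw score (`uniroot` on
[−35, 35]); they are undefined (flagged) at extreme raw scores.

### Item fit

Standardized residuals $z=(x-E)/\sqrt{E(1-E)}$ over non-extreme complete
persons give outfit (unweighted mean square) and infit
(information-weighted, $\sum(x-E)^2/\sum W$). Standardized statistics use
the Wilson–Hilferty cube-root transformation with the kurtosis-based
variance ($E[(x-E)^4]=W(1-3W)$ per Bernoulli cell). The per-item chi-square
is $\sum z^2$ on $n-1$ degrees of freedom (an assumption recorded here — fit
conventions differ), with the p-value multiplied by the number of items
(Bonferroni) and clipped at 1. Flag bands follow the screening literature:
mean squares outside (0.60, 1.40) or $|t| > 2.5$.

### Reliability

The person separation index is separation reliability,
$\mathrm{PSI} = (\mathrm{var}(\hat\theta) - \overline{SE^2}) /
\mathrm{var}(\hat\theta)$, clipped to [0, 1] and read like Cronbach's
alpha. Following the convention of the reference Rasch implementations
(e.g. eRm's separation reliability), the ability variance is taken over
*all* complete persons — extreme raw scores receive abilities extrapolated
linearly from the two adjacent interior scores — while $\overline{SE^2}$
averages the persons whose ML ability is defined. This matters: at this
scale's geometry roughly a third of persons endorse nothing, and excluding
them halves the apparent ability variance and drags the PSI from ~0.75 to
~0.45 — irreconcilable with how published PSIs of this instrument class are
computed. The mean inter-item Pearson correlation (pairwise-complete) is
reported alongside, as recommended for short scales (optimal range
0.20–0.40, though strongly bimodal traits push it higher).

## Dimensionality and local dependence

**Modified parallel analysis** (`modified_parallel_analysis()`): the
statistic is the second eigenvalue of the inter-item tetrachoric correlation
matrix; the Monte Carlo null simulates datasets from the fitted model and
$p = (1 + \#\{\lambda^{null}_2 \ge \lambda^{obs}_2\})/(n_{mc}+1)$ (add-one
rule, so $p$ is never zero; default $n_{mc} = 2000$ as in the validation
study). The null generator draws each person's pattern **conditionally on
their observed raw score** from the fitted conditional distribution
$P(x\mid r)\propto\prod_i\varepsilon_i^{x_i}$. This is the key design
choice: under the Rasch model the raw score is sufficient for $\theta$, so
the conditional draw requires no assumption about the latent-trait
distribution. Simulating instead from point-estimate abilities (one value
per raw score) distorts the null second-eigenvalue distribution in a
geometry-dependent direction and destroys the uniformity of $p$ under the
null; the conditional null is verified uniform by a Kolmogorov–Smirnov check
in the test suite, with full power against a two-factor alternative
(item subsets on traits correlated 0.2). The conditional sampler enumerates
patterns and therefore caps at 16 items.

Tetrachoric correlations are maximum likelihood on each 2×2 table (threshold
from the margins, correlation solving the both-positive cell), with a 0.5
continuity correction for empty cells. The bivariate normal CDF uses
32-point Gauss–Legendre quadrature of Plackett's identity, accurate to
~1e-10 against numerical integration. Non-positive-definite matrices are
smoothed by eigenvalue clipping (with a warning) and rescaling to unit
diagonal.

**Ponocny's T1** (`ponocny_t1()`): for each of the $\binom{7}{2}=21$ item
pairs the statistic counts persons answering both items identically; with
margins fixed this is a monotone function of the both-positive count, so
large values mean positive local dependence. The reference set — all 0/1
matrices with the observed row and column sums — is sampled by a compiled
Metropolis chain over 2×2 checkerboard swaps (`sample_fixed_margins()`);
the symmetric proposal makes the stationary distribution uniform, verified
against exhaustive enumeration on small matrices. Sampler defaults:
burn-in 1000 sweeps, thinning 16 sweeps, 500 samples, one sweep =
`nrow(matrix)` proposals; the one-sided p uses the add-one rule. Degenerate
matrices admitting no swap emit the observed matrix with a warning. The
discreteness of the statistic makes the test mildly conservative (null
rejection ~2.5% at nominal 5%), which the calibration tests bound in
[0.02, 0.09].

## Differential item functioning

`dif_logistic_item()` compares nested logistic models of the item on the
matching variable (the 7-item total score, including the studied item;
purification is not applied): `item ~ score` versus
`item ~ score + group + score:group`, a 2-df likelihood-ratio test covering
uniform and non-uniform DIF jointly (`uniform_only = TRUE` gives the 1-df
variant). The effect size is the Nagelkerke $R^2$ difference, clipped at
zero and classified negligible (< 0.035), moderate (0.035–0.07) or large
(> 0.07). Benjamini–Hochberg correction (via `stats::p.adjust`) is applied
within each grouping family across the seven items — eight families of
seven tests for the study's covariates (sex, median-split age 18–33 vs 34+,
interpreter use, support agency, Southern-Asian vs other origin, marital
status, travel mode, detention). Complete separation is detected (boundary
fitted probabilities or exploding coefficients) and all three likelihoods
are then recomputed with Firth's Jeffreys-prior penalty; such results carry
a `separation` flag. Calibration at the study geometry: type-I rate within
[0.03, 0.08] at $n=1000$, and >80% power for a 1-logit injected shift —
though the accompanying $\Delta R^2$ for a 1-logit shift is typically below
the 0.035 "moderate" line at $n=1000$, so significance and effect size are
deliberately reported separately.

## Diagnostic accuracy

`roc_points()` builds one operating point per observed threshold
("score ≥ c") plus the endpoints; the trapezoid AUC equals the Mann–Whitney
concordance with half-credit for ties (verified exactly against brute-force
pairwise comparison). `auc_with_ci()` adds the DeLong
structural-components variance and a Wald interval clipped to [0, 1]
(cross-checked against pROC in the tests). `optimism_corrected_auc()`
implements Harrell's algorithm with the univariable logistic model
`caseness ~ score` and 200 resamples (the study's choice); single-class
resamples are redrawn and counted. Because the model is monotone in one
predictor, the apparent AUC equals the score's rank AUC and the correction
measures sampling optimism only.

`cutoff_table()` reports, per cut-score, the 2×2 counts, SN, SP, PPV, NPV
and efficiency (raw accuracy) with Clopper–Pearson 95% intervals
(`binom.test`), likelihood ratios with log-method intervals, and the Youden
sum SN + SP — the scale on which the study prints its "Youden's J" column
(the conventional J = SN + SP − 1 is emitted alongside). Perfect
specificity flags an infinite PLR; perfect sensitivity gives NLR 0.
`youden_select()` picks the cut-score maximizing the Youden sum (ties to
the lower cut-score) and the *sensitivity-privileged* cut-score: the highest
cut-score whose sensitivity still meets the floor (default 0.90), i.e.
maximal specificity subject to the sensitivity constraint — the rationale
by which the study preferred ≥2.

## The synthetic cohort generator

No raw responses are deposited, so `simulate_cohort()` emulates the study
conditions: caseness ~ Bernoulli(0.33); distress trait
$\theta \sim N(-2.5, 1.5^2)$ for non-cases and $N(+1.0, 1.5^2)$ for cases;
scale responses from the Rasch model at the published difficulties;
screen-in items Bernoulli(0.35 | case, 0.05 | non-case) — ansatz values, the
study describes no generative model for them; covariates from the study's
marginal frequencies only (no joint dependence); MCAR missingness last
(`missing_rate` is per cell; 0.036/9 makes ~3.6% of 192 persons incomplete,
the study's omission rate). A caseness-linked normal mixture was chosen over
a logistic link on $\theta$ because it is directly tunable to the observed
separation.

The mixture was calibrated **once** on a grid (`analysis/00_tune_generator.R`)
against four published anchors simultaneously: per-item endorsement ~31%,
7-item AUC ~0.912 at 33% prevalence, mean inter-item correlation ~0.46, and
PSI ~0.75 at n = 185. Trait SD 1.5 is the unique grid setting meeting all
four — narrower spreads reproduce endorsement and AUC but not the
correlation/PSI pair. What the generator does *not* emulate: real items'
unequal discrimination, covariate-dependent traits, informative
missingness, and any screen-in/scale dependence beyond shared caseness. So
passing tests demonstrate correctness of the *procedures* at a realistic
geometry, not validity of the instrument in new populations.

Two geometry notes that shape the tests: (i) with ~a third of persons at raw
score 0, CML standard errors at n = 1000 are ~0.09, so recovered
difficulties (true spread only ±0.4 logits) correlate with truth at ~0.94
under cohort defaults; recovery accuracy is therefore asserted as RMSE
there, and the r > 0.95 correlation check runs under a centered trait
N(0, 1.5²), where RMSE < 0.10 also holds. (ii) At n = 185 the sample Youden
optimum fluctuates between cut-scores 2 and 3 across cohorts — the same
instability that led the study to prefer the sensitivity-privileged ≥2.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible
under it (cohorts, the swap chain, Monte Carlo nulls, bootstrap). The test
suite sizes its simulations to stay deep but quick: calibration checks use
cohorts of 150–1000 persons with 60–400 replicates and Monte Carlo nulls of
120–300 samples; the full-scale settings (2000 parallel-analysis samples,
500 sampler draws, 200 bootstrap resamples) are the defaults used by the
analysis scripts and the acceptance script. The pipeline
(`run_validation_report()`) derives all stage seeds from one master seed and
rerunning with the same seed reproduces every written table byte for byte.

## Known limitations

- Polytomous models are out of scope; Likert input exists only as a
  dichotomization source (threshold ∈ {2, 3, 4}, study convention ≥3).
- The conditional-null parallel analysis and T1 both require complete cases;
  persons with missing scale responses are dropped first, as in the study.
- CART retention is backed by `rpart` (Gini, `cp = 0`, depth/leaf controls
  exposed); tie-breaking between equally good splits follows rpart's
  deterministic internal order rather than an item-index rule.
- The Firth fallback in DIF handles separation but small-sample penalized
  LR tests remain approximate; flagged rows deserve inspection.
- Fit-statistic degrees of freedom (chi-square on n − 1) and CI conventions
  (Clopper–Pearson, log-method) are explicit choices among several in use;
  all are recorded in the output metadata or documented here.
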