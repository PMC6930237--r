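---
title: "Methods: QC and design-based regression for environment-wide association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC and design-based regression for EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewaspipe)
```

## The problem

An environment-wide association study (EWAS) regresses one phenotype on each
of hundreds of exposure variables in turn — questionnaire items, nutrient
levels, lab measures — the exposome analogue of a GWAS. Two things make this
harder than it sounds. First, exposure tables are a mess of mixed types
(binary, categorical, continuous), sentinel-coded missingness, and
degenerate variables, and cleaning them by hand is irreproducible. Second,
the major health surveys these data come from (NHANES and its relatives) use
stratified, clustered, weighted sampling: treating the sample as simple
random data biases both estimates and standard errors.

`ewaspipe` covers the full path: typed data management with an audit trail,
reproducible QC filters, per-exposure regression honoring the sampling
design, multiple-testing correction, and category-grouped Manhattan plots —
with a synthetic survey generator so the whole chain is testable against
known truth.

## Variable typing and QC filters

`categorize()` assigns each variable a type from its number of distinct
non-missing values *u*:

| *u* | type |
|-----|------|
| 0 | empty |
| 1 | constant |
| 2 | binary |
| 3–5 | categorical |
| 6–14 | check (manual review via `recode_type()`) |
| ≥ 15 and numeric | continuous |

The 3/5/15 defaults are the conventional cut points for survey exposure
data; all three are tunable through `categorize_thresholds()`. Two choices
here were genuinely open and are worth stating:

* **Missing values never count as a level.** A sentinel-cleaned missing
  state is not a category, so typing is computed on non-missing tokens only.
* **Continuous additionally requires numeric coercibility.** A
  high-cardinality string variable (free text, dates) goes to `check`
  rather than being silently coerced to `NA`s.

The filters mirror their verbal definitions exactly at the boundaries:

* `colfilter_min_n(min_n = 200)` drops variables with *fewer than* 200
  non-missing values — 199 is dropped, 200 kept.
* `colfilter_min_cat_n(min_cat_n = 200)` drops a binary/categorical
  variable unless *every* observed level has at least 200 occurrences — a
  200-count level survives.
* `colfilter_percent_zero(threshold = 0.90)` drops a continuous variable
  when *more than* 90% of its non-missing values are zero — exactly 90%
  survives. The denominator is the non-missing count, so missingness cannot
  rescue a degenerate variable (configurable in principle by pre-filtering;
  the choice is deliberate and conservative).

`drop_degenerate()` removes constant/empty variables ahead of the
sample-size filters so each filter's removals are attributable to its own
rule. Filters never alter cell values, are idempotent, and each appends one
provenance entry; `min_n` and `min_cat_n` commute.

## The regression model

For each exposure $X$ the model is

$$Y = \beta_0 + \beta_1 X + \beta_2\,\mathrm{cov}_1 + \dots + \beta_{n+1}\,\mathrm{cov}_n + \varepsilon ,$$

fit on the complete cases for that exposure's own model (outcome,
covariates, $X$, and $X$'s weight), after discarding zero-weight rows.
Exposures are tested marginally, never jointly. If fewer than `min_n`
(default 200) rows remain, the exposure gets a NULL row with a skip reason
rather than an unstable fit. Continuous and binary exposures report one
coefficient, its SE and a two-sided p-value; binary exposures are coded 0/1
with the lexicographically smaller level as reference.

Categorical exposures ($k \ge 3$ observed levels; a 2-level subset falls
back to the binary path) report a single term p-value:

* **Without a design**: a likelihood-ratio test of the full against the
  reduced (covariates-only, or intercept-only when there are no covariates)
  model, $\Lambda = 2(\ell_{full} - \ell_{reduced}) \sim \chi^2_{k-1}$,
  both models fit on the identical rows. For the gaussian family the
  log-likelihood uses the ML variance, so on a one-way layout $\Lambda =
  n\log(1 + (k-1)F/(n-k))$ — the classical ANOVA F-test's monotone
  transform, which the tests verify.
* **With a design**: a Wald F test of joint nullity of the $k-1$ dummy
  coefficients using the linearized covariance, $F = \beta_g^\top
  \hat{V}_g^{-1} \beta_g / (k-1)$ with denominator df as below. The
  pseudo-likelihood ratio is not $\chi^2$-calibrated under unequal weights,
  which is why the design path defaults to Wald; `categorical_test = "lrt"`
  switches back for users who want the working LRT regardless.

## Design-based variance

Point estimates maximize the weighted pseudo-likelihood
$\sum_i w_i\,\ell_i(\beta)$: closed-form weighted least squares for the
gaussian family, IRLS (score tolerance $10^{-8}$, 25 iterations,
non-convergence flagged rather than raised) for the binomial. Point
estimates are invariant to positive rescaling of the weights, and so is the
covariance.

`linearized_covariance()` implements Taylor-series linearization in the
with-replacement approximation: $\hat{V} = A^{-1} B A^{-1}$ with the
weighted information $A = \sum_i w_i v_i x_i x_i^\top$ and

$$B = \sum_h \frac{n_h}{n_h - 1} \sum_{c}
   (z_{hc} - \bar{z}_h)(z_{hc} - \bar{z}_h)^\top ,
 \qquad z_{hc} = \sum_{i \in c} w_i\,(y_i - \hat\mu_i)\,x_i ,$$

where $n_h$ counts the PSUs in stratum $h$. No finite-population correction
is applied — public-use designs for the surveys this targets are analyzed
as with-replacement draws. With one stratum, singleton PSUs and unit
weights this collapses to the heteroskedasticity-robust sandwich times
$n/(n-1)$ (because OLS residuals are orthogonal to the design matrix, the
cluster-total means vanish), a reduction the tests check to $10^{-10}$.

**Degrees of freedom.** Inference uses a $t$ reference with
$df = (\#\mathrm{PSUs} - \#\mathrm{strata}) - (p - 1)$, floored at 1, where
$p$ is the number of estimated coefficients — the de-facto convention of
design-based GLM software. Without a design, the residual df is used. This
convention matters: with 30 PSUs in 15 strata and 7 adjustment columns the
reference has 8 df, and ignoring it would overstate significance.

**Lonely PSUs.** A stratum with a single sampled PSU has no within-stratum
variance estimate. The default policy is `fail` (loud error beats silent
variance distortion); `adjust` centers the lonely stratum's score total at
the grand mean of all cluster totals (with unit factor, since $n_h/(n_h-1)$
is undefined at $n_h = 1$); `certainty` lets the stratum contribute
nothing.

## Multiple testing

`add_corrected_pvalues()` attaches Bonferroni ($\min(1, m\,p)$) and
Benjamini–Hochberg step-up q-values through `stats::p.adjust`, with $m$ =
the number of tests actually computed — NULL rows are excluded from $m$ and
receive no corrected values. An explicit `m` can be supplied when the table
is a subset extracted from a larger family (this is how the package
reproduces published corrected values from printed top-hit tables). The BH
choice for the FDR gate is a decision: the discovery-gate FDR estimator is
rarely stated in applied EWAS reports, and BH is the standard default.

## Manhattan plots

`manhattan_coordinates()` is pure computation — category-blocked integer x
positions (categories sorted, `unknown` last, variables sorted within a
block), $y = -\log_{10}(p)$ of the *raw* p-value, per-dataset Bonferroni
lines at $-\log_{10}(\alpha/m)$ (correction lives in the line, not the
points), an FDR line at the largest passing raw p when any test passes, and
label flags for variables crossing the Bonferroni line in every dataset
they appear in. `render_manhattan()` only draws that table; every numeric
assertion in the tests targets the table, never pixels. Zero p-values are
capped at $y = 320$ (just past double underflow) and flagged.

## The synthetic survey generator

`generate_survey_dataset()` emulates the data regime the pipeline targets:

* a finite population (3× the target sample by default) in 15 strata × 2
  PSUs — the shape of a national health-survey cycle — with cluster random
  intercepts (SD 0.25);
* mixed exposures (35 continuous, 10 binary, 5 three-level categorical by
  default), covariates age ~ N(45, 15), sex ~ Bernoulli(0.5), race ~
  five categories at realistic frequencies;
* a linear continuous outcome with unit residual SD; default true effects
  $\beta = 0.3$ on ten continuous exposures, categorical effects expanded
  to level offsets summing to zero (identifiability);
* **informative Poisson sampling**: inclusion log-odds increase by
  $2\gamma$ per SD of the outcome, scaled to the target sample size, with
  inclusion probabilities bounded to $[0.05, 0.99]$; weights are exact
  inverse inclusion probabilities. At $\gamma = 1$ the unweighted slope
  estimator is biased by roughly $-0.14$ at $\beta = 0.5$ while the
  weighted estimator is essentially unbiased — strong enough that ignoring
  the weights is visibly wrong, which is the point of the fixture. The
  log-odds scale (2 per SD) and the probability floor are design choices
  made once: the floor is the textbook positivity requirement and keeps the
  inverse-probability variance finite; without it, weights in the hundreds
  make linearized intervals undercover at 30 PSUs.

`generate_filter_tripwires()` builds the QC test-bed: one variable
engineered per filter (199 non-missing; a 150-count level; 95% zeros; 8
distinct values; a constant; an all-missing column) plus the exact boundary
survivors (200 non-missing; a 200-count level; exactly 90% zeros) and clean
variables of every type. Its truth record names each tripwire and the rule
expected to remove it, so the expected outcome of the whole QC chain is
recomputable without reading generator code.

What the generator does **not** emulate: real codebook semantics,
multi-cycle weight construction, non-linear exposure–outcome relationships,
informative *missingness* (missingness is MCAR), and measurement error.
Passing tests therefore demonstrate correctness of the mechanics —
typing, filtering, weighting, variance, correction — not robustness to
every failure mode of real survey data.

## Numerical choices and problem sizes

* Weighted solves go through QR, never the normal equations; rank
  deficiency is reported with the offending columns.
* IRLS: score tolerance $10^{-8}$, max 25 iterations, variance weights
  floored at $10^{-10}$ near saturation.
* All generation is seeded (Mersenne-Twister/Inversion pinned), so
  identical inputs give bit-identical result tables.
* The calibration studies in the test suite use 1,000 null replicates
  (type-I error) and 500 effect replicates (CI coverage) at $n = 2{,}000$
  per replicate, 200 replicates for the bias-halving check, and single
  fixtures of $n = 10{,}000$ for the degenerate-design reduction — sizes
  chosen to put Monte-Carlo error well inside the asserted bands.

## Known limitations

* No replicate-weight variance (BRR/jackknife), post-stratification,
  raking, or multistage finite-population corrections.
* No ordinal or multinomial outcomes, no interaction terms.
* The working LRT under a design is available but not calibrated; the Wald
  F is the supported design-based term test.
* Exact reproduction of published full-scale survey analyses additionally
  depends on conventions (df, lonely-PSU handling, FDR variant) that
  applied reports rarely state; the package documents its own conventions
  prominently instead.
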