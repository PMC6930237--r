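# ewaspipe

Quality control and survey-weighted regression for environment-wide
association studies (EWAS).

An EWAS regresses a phenotype on each of hundreds of exposure variables in
turn — the exposome analogue of a GWAS. `ewaspipe` is for analysts working
with mixed-type exposure tables from complex-design health surveys
(NHANES-style: strata, primary sampling units, inverse-probability weights)
who need the cleaning and the analysis to be reproducible end to end. It
provides:

* **Typed data management** — a `raw_dataset` of tokens with a single
  missing state, sentinel standardization from a user map, merges, sample
  filters, transforms, and an append-only provenance log;
* **Type inference and QC** — variables classified by distinct-value count
  (2 → binary, 3–5 → categorical, ≥ 15 numeric → continuous, 6–14 → manual
  `check` queue), then filtered by minimum sample size (< 200 dropped),
  minimum per-category count (every level ≥ 200), and percent-zero
  (> 90% zeros dropped), each rule exact at its boundary;
* **Design-based EWAS** — one model per exposure,
  `Y = β₀ + β₁X + β₂cov₁ + … + βₙ₊₁covₙ`, fit by weighted maximum
  pseudo-likelihood with Taylor-series linearization (sandwich) variance
  over cluster totals of weighted scores,
  `V = A⁻¹[Σₕ nₕ/(nₕ−1) Σ_c (z_hc − z̄ₕ)(z_hc − z̄ₕ)ᵀ]A⁻¹`,
  t/Wald-F inference on `(#PSU − #strata) − (p − 1)` df, per-variable weight
  maps, explicit lonely-PSU policies, and LRT term tests for categorical
  exposures without a design;
* **Multiple testing** — Bonferroni and Benjamini–Hochberg columns with the
  family size `m` counting only tests actually computed;
* **Visualization** — category-grouped Manhattan plots (coordinates and
  rendering strictly separated) and per-variable distribution plots;
* **A synthetic survey generator** — stratified two-stage samples with
  informative (outcome-dependent) Poisson sampling, known effect sizes, and
  a truth record, plus a QC "tripwire" fixture with one variable engineered
  to trip each filter.

## Worked example

Generate a survey with known truth (effects β = 0.3 on `cont01`–`cont10`),
type it, build the design, and run the weighted EWAS:

```r
library(ewaspipe)

gen   <- generate_survey_dataset(generator_params(seed = 42))
typed <- categorize(gen$data)
type_counts(typed)
#>      binary categorical  continuous       check    constant       empty
#>          11           6          38           2           0           0

design <- build_design(gen$data, strata_var = "stratum",
                       cluster_var = "psu", weight_spec = "weight")
design
#> survey_design: 1981 samples, 15 strata, 30 PSUs
#>   clusters per stratum:  2 PSU x 15
#>   weight 'weight': range [1.501998, 20], 0 missing
#>   lonely PSU policy: fail

res <- ewas(typed, outcome = "outcome",
            covariates = c("age", "sex", "race"),
            design = design, family = "gaussian", min_n = 200)
res <- add_corrected_pvalues(res)
head(as.data.frame(res[order(raw_pvalues(res)), c("variable", "type", "n",
     "beta", "se", "pvalue", "pvalue_bonferroni")]), 5)
#>  variable       type    n  beta     se   pvalue pvalue_bonferroni
#>    cont02 continuous 1981 0.273 0.0310 2.15e-05           0.00108
#>    cont10 continuous 1981 0.315 0.0401 4.93e-05           0.00246
#>    cont01 continuous 1981 0.353 0.0475 7.32e-05           0.00366
#>    cont04 continuous 1981 0.256 0.0361 1.03e-04           0.00515
#>    cont03 continuous 1981 0.269 0.0398 1.43e-04           0.00717
```

The top hits are true-effect exposures with betas near 0.3 and small
standard errors from the linearized covariance; `pvalue_bonferroni` is the
raw p times the 50 computed tests, capped at 1. The two `check` variables
are the stratum/PSU label columns (high-cardinality strings), which the
typer correctly refuses to call continuous. A Manhattan plot of one or more
result tables comes from `manhattan_coordinates()` + `render_manhattan()`.

The same workflow is scriptable from a shell via the bundled CLI
(`inst/cli/ewaspipe.R`): `synth`, `categorize`, `recode`, `filter`,
`modify`, `describe`, `ewas`, `correct`, `plot` subcommands over TSV files
with a type sidecar, so a pipeline is resumable from files alone.

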