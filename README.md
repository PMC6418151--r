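# egodelay

Egocentric (personal) social-network analysis of delayed hospital arrival
after acute stroke.

Most strokes happen in front of other people, and the decision to go to
the hospital is negotiated with them. This package implements the full
quantitative pipeline for studying that social context: per-patient
network metrics from survey-derived rosters, cohort-level statistics with
covariate adjustment, sensitivity analyses, and a calibrated synthetic
cohort generator so the entire pipeline is testable without patient-level
data (which studies of this kind typically cannot release).

## The measures

For one patient (the *ego*) with $n$ named contacts (*alters*), tie-weight
matrix $z$ and tie proportions
$p_{ij} = (z_{ij}+z_{ji}) / \sum_k (z_{ik}+z_{ki})$:

* **Network size** $n$ (ego excluded);
* **Burt constraint** $C = \sum_j (p_{ej} + \sum_{q\ne e,j} p_{eq} p_{qj})^2$,
  reported as $100\,C$ — high in small, dense, strongly tied ("close-knit")
  networks with few structural holes;
* **Effective size** $E = \sum_j (1 - \sum_q p_{eq} m_{jq})$,
  $m_{jq} = z_{jq}/\max_k z_{jk}$ — the number of nonredundant contacts;
* **Mean degree** of the alter–alter subgraph;
* Composition: percent kin, SD of alter ages, index of qualitative
  variation $(1-\sum p_i^2)/(1-1/k)$ for sex and race, percent
  nonexercisers, percent with prior stroke.

Cohort analysis compares slow (arrival past a 6 h cutoff) and fast
arrivers, then fits block-wise logistic regressions per network metric
(covariates first — age, NIHSS, EMS use, living alone, education, Black
race, median income — then covariates + one metric), reporting adjusted
odds ratios with Wald 95% CIs and log-likelihoods for nested comparison.
Sensitivity analyses re-run everything at a 3 h cutoff, without very small
networks, stratified by race, and with a metric-by-race interaction.

## Worked example

```r
library(egodelay)

# a calibrated synthetic cohort: 67 slow / 108 fast arrivers
cohort <- generate_cohort(paperlike_config(), seed = 1)
metrics <- metrics_table(cohort)

# unadjusted group contrast in constraint (0-100 scale)
slow <- cohort$patients$arrival_hours_gt_cutoff
round(c(median(metrics$constraint_x100[slow]),
        median(metrics$constraint_x100[!slow])), 2)
#> [1] 63.02 43.13

# covariate-adjusted odds ratio of delayed arrival per unit network size
blockwise_models(cohort, "size", metrics = metrics)
#> # A tibble: 1 × 9
#>   metric    or ci_low ci_high p_value loglik_base loglik_full     lr_p n_used
#>   <chr>  <dbl>  <dbl>   <dbl>   <dbl>       <dbl>       <dbl>    <dbl>  <int>
#> 1 size   0.857  0.776   0.946 0.00213       -105.       -98.4 0.000349    175
```

A slow-group constraint median near 63 against a fast-group median near 43
reproduces the close-knit-network contrast the generator encodes, and the
adjusted OR below 1 says each additional network member lowers the odds of
delayed arrival, independent of the seven covariates. `forest_table()`
runs all ten metrics in the canonical reporting order;
`sensitivity_suite()` produces the four robustness re-analyses;
`cmd_simulate()` / `cmd_metrics()` / `cmd_analyze()` / `cmd_sensitivity()`
/ `cmd_montage()` are the file-level pipeline verbs (also callable from a
shell via `inst/cli/egodelay.R`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates a calibrated cohort from the installed package, runs every
pipeline verb over it (metrics, analysis tables, sensitivity suite,
montage layout), prints the adjusted odds-ratio table it computed, and
writes the acceptance-report JSON to `--out`.
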