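---
title: "Ego networks and delayed hospital arrival: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ego networks and delayed hospital arrival: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egodelay)
```

## The problem

Most strokes happen in the presence of other people, and the decision to
seek care is usually negotiated among the patient and the people around
them. Whether a patient reaches the hospital inside a treatment window is
therefore not only a property of the patient (age, severity, EMS access)
but of their *personal network*: the set of people they confide in, how
those people are connected to each other, and how alike they are.

`egodelay` implements a complete analysis pipeline for this question. Its
unit of data is the **egocentric network**: one patient (the *ego*)
surrounded by the people they named in a survey (*alters*), the strength of
each patient–alter tie (strong/weak), and the alter–alter ties the patient
reported. The outcome is binary delayed arrival — onset-to-door time beyond
a cutoff (6 h primary, 3 h in sensitivity analyses).

## Network measures

### Structure

Let $z_{ij} \ge 0$ be the symmetric tie-weight matrix over the ego and its
$n$ alters (the diagonal is 0), and let

$$p_{ij} = \frac{z_{ij} + z_{ji}}{\sum_{k} (z_{ik} + z_{ki})}$$

be the proportion of $i$'s total tie weight spent on $j$.

* **Network size** $n$ — the number of alters, ego excluded.
* **Burt constraint**
  $C = \sum_j \Big(p_{ej} + \sum_{q \ne e,j} p_{eq}\,p_{qj}\Big)^2$,
  summed over alters $j$ with $e$ the ego. It rises with density, strong
  ties, and hierarchy, and falls with size. We report $100\,C$: on this
  scale an isolated dyad scores 100, a star of $n$ alters $100/n$, and an
  equal-weight clique $100\,(2n-1)^2/n^3$.
* **Effective size**
  $E = \sum_j \big(1 - \sum_{q \ne e,j} p_{eq}\, m_{jq}\big)$ with
  $m_{jq} = z_{jq} / \max_{k \ne e,j} z_{jk}$: the number of
  *nonredundant* contacts. $E = n$ for a star, 1 for an equal-weight
  clique, and on any single-weight network $E = n - 2t/n$ where $t$ is the
  number of alter–alter ties.
* **Mean degree** — the average number of alter–alter ties per alter.

Two conventions deserve comment because the verbal definitions are
ambiguous:

* *Mean degree* is computed on the alter–alter subgraph with the ego
  excluded both as a node and from the edge set, so a pure star scores 0.
  An `include_ego_tie = TRUE` mode adds 1 per alter for comparability
  studies.
* In $m_{jq}$ the maximisation runs over $j$'s alter neighbours only. This
  choice makes the binary identity $E = n - 2t/n$ exact, which the test
  suite exploits as an independent check.

Both constraint and effective size are invariant to uniformly rescaling
all tie weights, so only the strong:weak ratio matters. The default coding
is `tie_weights(1, 0.5)` — the conventional 2:1 — and it is configurable.
The implementation is verified against a brute-force summation oracle on
every equal-weight graph with up to 5 alters (exhaustive enumeration), and
against `igraph::constraint()` as an independent reference.

### Composition

* **Percent kin**, **percent nonexercisers**, **percent with prior
  stroke** — shares among alters with a known value (pairwise deletion; no
  imputation, because none is described for the source data).
* **SD of alter ages** — sample standard deviation ($n-1$ denominator; a
  conventional choice, configurable in principle, requiring at least two
  known ages).
* **Index of qualitative variation** for sex and race:
  $\mathrm{IQV} = (1 - \sum_i p_i^2)/(1 - 1/k)$, 0 for a homogeneous
  network and 1 at the uniform mix over $k$ categories. For sex $k = 2$.
  For race, $k$ defaults to the size of the race codebook rather than the
  number of categories observed in the network, so a homogeneous network
  scores 0 regardless of codebook — consistent with race-diversity medians
  of 0 in cohorts recruited from racially segregated catchments.

## Statistical pipeline

1. **Descriptive comparison** (`compare_groups()`): slow vs fast arrivers,
   one test per declared variable. Continuous variables use a Welch t test
   unless the variable is on a declared Wilcoxon list (education and income
   by default — skewed survey quantities). The "nonparametric if needed"
   rule is operationalised as a *declared list*, not a normality autotest,
   for determinism. Categorical variables use the chi-squared test with
   continuity correction unless any *expected* cell count is below 5
   (Cochran's rule), in which case Fisher's exact test is used.
2. **Unadjusted network comparison** (`network_comparisons()`): median
   [IQR] per group and Wilcoxon rank-sum p for each of the ten metrics
   (exact p where ties allow, normal approximation with tie correction
   otherwise — R's default).
3. **Adjusted block-wise models** (`blockwise_models()`,
   `forest_table()`): per network metric, block 1 is a logistic regression
   of delayed arrival on the covariate set (age, NIHSS, EMS use, living
   alone, education years, Black race, median household income — the four
   literature risk factors plus three socioeconomic controls), block 2
   adds the single metric. Metrics enter one at a time because they are
   strongly collinear. Both blocks are fitted on the same complete-case
   rows so the log-likelihoods are comparable; the headline OR/CI/p are
   Wald ($\exp(\hat\beta \pm 1.96\,\mathrm{se})$, the default of standard
   software), with the 1-df likelihood-ratio p exposed alongside. No
   multiplicity adjustment: each metric is its own pre-declared test at
   $p < 0.05$.
4. **Sensitivity analyses** (`sensitivity_suite()`): (a) a 3 h cutoff —
   this *relabels* the outcome from the continuous `arrival_hours` field,
   which is why the patient schema carries that optional column; (b)
   removal of networks with fewer than four members; (c) stratification by
   Black race (the race indicator is dropped from the stratified covariate
   set, being constant within stratum); (d) an interaction model adding a
   metric-by-race product term.

Failure modes are explicit rather than silent: a constant outcome or
predictor raises a classed `egodelay_degenerate_fit` condition naming the
variable, and separation (diverging coefficients or standard errors after
a `glm` boundary warning) raises `egodelay_separation`. Table-level
drivers (`forest_table()`, `sensitivity_suite()`) convert these into
status rows so one degenerate stratum never destroys a report.

## The synthetic cohort: a stated world

No patient-level data ship with the package, so every pipeline stage is
exercised against a synthetic cohort whose parameters are **documented
constants**, fixed once from the published group-level summaries and never
fitted at run time:

* Two groups of 67 slow / 108 fast arrivers. The group label is drawn
  first and drives everything else (outcome-first simulation, matching the
  case-control-style contrast of the design); a continuous arrival time is
  drawn consistently with the label (slow: 6 h + an exponential with mean
  6 h; fast: 6 h times a Beta(1, 1.5)) so alternative cutoffs can relabel
  the outcome.
* Network size is discretised log-normal: median 5 (slow) vs 8 (fast),
  log-dispersions 0.51/0.45 back-solved from the printed IQRs. Alter–alter
  ties are independent Bernoulli draws at density 0.92 (slow) vs 0.72
  (fast), tie strengths Bernoulli at strong-fractions 0.80/0.60 — chosen so
  the group constraint medians sit near the reported 61/40 on the 0–100
  scale. Alter attributes are independent draws: kin 0.62/0.57, ages
  normal around the ego's age with SD 12.0/13.5 years, nonexercisers
  0.62/0.44, 65% female, race equal to the ego's with probability 0.95
  (anchoring race IQV near 0), prior stroke 0.15 (a figure not reported by
  group; a plausible community prevalence among older adults' contacts).
* Covariates mirror the printed group summaries: age ~ N(61.0, 15.9) vs
  N(61.7, 15.6); NIHSS ~ Poisson(3) truncated at 12/13; EMS 0.55/0.69;
  living alone 0.33/0.25; married 0.36/0.48; education ~ round N(14, 2.2);
  income log-normal with medians 39.0/48.9 ($1000) and log-sd 0.39 (from
  the printed IQRs); Black race 0.42/0.25; thrombolysis 0 (slow) / 0.50
  (fast).

The independent-Bernoulli tie model is chosen for transparency and
closed-form reasoning, not realism: real personal networks show kin
clustering, degree correlation, and correlated attribute/tie structure
that this generator deliberately omits, and within a group the covariates
are independent of the network. A green calibration test therefore
establishes that the *pipeline* recovers what this stated world puts in —
it does not validate the generator as a model of real cohorts, nor
reproduce the original cohort-level estimates, which depend on unreleased
patient-level data.

Because the outcome-first generator has no single "true odds ratio", the
package also provides an outcome-*second* simulator
(`generate_logistic_cohort()`): networks and covariates are drawn from one
shared parameter set and the outcome is then drawn from a logistic model
with a specified conditional OR for one metric (the published point
estimates 0.83 for size and 1.04 for constraint serve as simulation
truths). This is the mode under which CI coverage and parameter recovery
are well-defined and tested.

## Numerical and design choices

* **Tie-weight scale.** Only the ratio matters (proved by a
  scale-invariance property test); 2:1 is the default coding.
* **Empty networks** yield missing structural metrics (an undefined-metric
  signal, not an error); the patient stays in descriptive tables and drops
  from models using the metric, with `n_used` reported.
* **Canonical tie storage**: unordered pairs stored with
  `alter_a < alter_b` and sorted, making file round-trips byte-stable and
  order-irrelevant.
* **Determinism.** Every verb is reproducible given seed + config; the run
  manifest records a config hash computed over key-sorted canonical JSON
  (stable under key reordering) plus a wall-clock timestamp, which is the
  one manifest field excluded from reproducibility comparisons.
* **Reference contingency value.** The published race comparison prints
  p = 0.0309 labelled as Fisher's exact; on the printed table Fisher's
  two-sided p is 0.0289, while 0.0309 is exactly the continuity-corrected
  chi-squared p. Since the declared selection rule picks chi-squared here
  (all expected cells ≥ 21), the pipeline reproduces the printed value via
  that route, and the Fisher routine is verified separately against a
  hypergeometric enumeration oracle.
* **Stratified subgroup counts.** The published stratified analyses report
  57/124 Black/non-Black while the baseline table implies 55/120; the
  reconciliation is not derivable, so stratification here acts on the
  single `race_black` field as recorded.
* **Report rounding**: percents to integers, ORs and CI bounds to 2
  decimals, p values to 4 — in the written report tables only; library
  functions return full precision.

## Limitations

* The generator's independence assumptions (above) bound what calibration
  can establish.
* Wald inference in the block-wise models is standard but can undercover
  in small strata; degenerate strata are flagged rather than rescued
  (e.g., penalised fits are out of scope).
* The survey instrument itself (name generator phrasing, roster caps) is
  not modelled; network size is unbounded in the data model.
* No survival-style modelling of continuous arrival time: the binary
  outcome at a cutoff is a design commitment of the source study, kept
  here.
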