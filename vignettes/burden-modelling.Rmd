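---
title: "Probabilistic disease-burden modelling of drinking-water contaminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic disease-burden modelling of drinking-water contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwburden)
```

## The model

`dwburden` quantifies the human-health burden of chemicals of emerging
concern (CECs) — pesticides, industrial chemicals, pharmaceuticals,
antibiotics, disinfection byproducts (DBPs) and personal care products —
in drinking water, and compares alternative treatment systems on that
basis. The burden unit is the disability-adjusted life year (DALY),
which combines mortality and disability into a single measure.

For each chemical $i$ and endpoint $j$ (cancer or non-cancer), the
population health effect over the plant's service horizon is

$$HE_i^j = EF_i^j \times DF^j \times IF_i^{ing},$$

where $EF_i^j$ is the effect factor (change in lifetime disease
probability per kg of lifetime intake, cases/kg), $DF^j$ the damage
factor (DALYs per case), and $IF_i^{ing}$ the mass of chemical $i$
ingested by the served population via drinking water:

$$IF_i^{ing} = SP \times IR_{ing} \times CE_i,$$

with $SP$ the population served, $IR_{ing}$ the cumulative per-capita
water intake over the horizon, and $CE_i$ the residual concentration
after treatment:

$$CE_i = CS_i \times \prod_k (1 - R_i^k).$$

$CS_i$ is the source-water concentration and $R_i^k$ the removal
fraction of unit process $k$. Only the ingestion pathway is modelled;
inhalation and dermal exposure to waterborne chemicals are small by
comparison and out of scope, as are dose–response nonlinearity and
age-stratified exposure.

Totals are reported per person and per year, $HE / (SP \times T)$, the
scale on which the WHO tolerable burden of
$1.00 \times 10^{-6}$ DALYs person$^{-1}$ year$^{-1}$ is defined. Note
that $SP$ and $T$ cancel algebraically in the per-person annual total;
they are retained in the interface because the intermediate quantities
(population intake, horizon totals) are meaningful outputs of their own.

### Default exposure constants

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `sp` | 500,000 | persons | population served by the plant |
| `ir_daily` | 1.4 | L/day | average drinking-water ingestion |
| `years` | 25 | y | plant service / exposure horizon |
| `df_cancer` | 11.5 | DALYs/case | cancer damage factor |
| `df_noncancer` | 2.7 | DALYs/case | non-cancer damage factor |
| `threshold` | 1e-6 | DALYs/person/y | tolerable burden |

### Mixture toxicity

Per-chemical burdens are combined additively by default — the
conservative convention when interaction data are scarce. Two
alternatives are available for comparison: *dominant* (the worst single
contributor, i.e. the maximum) and *multiplicative* (independent action:
per-person lifetime case probabilities $p_i$ combine as
$1 - \prod_i(1 - p_i)$, converted back to an annual burden with the
endpoint damage factor). The three orderings satisfy
dominant $\le$ multiplicative $\le$ additive for any non-negative
inputs, and the multiplicative total converges to the additive one for
small risks; both properties are asserted in the test suite. The
dominant and multiplicative conventions are this package's explicit
definitions of those terms, chosen because "dominant" conventionally
means the worst contributor and response addition is the standard
independent-action form.

## Data preparation rules

* **Censoring.** Concentrations reported below a detection (LOD) or
  quantification (LOQ) limit are set to half the limit — a conservative
  standard practice. In the CSV schema a censored record has blank
  concentration cells and a populated `lod` (or `loq`) column; LOD takes
  precedence when both are present, since the two limits are treated
  identically downstream. The rule is idempotent.
* **Removal imputation.** When a unit process has no measured removal
  for a chemical, the missing (low, mode, high) triple is imputed as
  the element-wise mean of the same-category chemicals that do have
  data in that unit. Averaging the distribution parameters (rather than
  pooling samples) keeps the imputation reproducible and keeps imputed
  triples inside $[0, 1]$ whenever the donors are. If a unit has no
  same-category donor at all, loading fails loudly rather than guessing.
* **Validation.** Removal fractions outside $[0, 1]$, negative
  concentrations and inverted triples are errors at load time, with row
  context; nothing is silently clipped.

## Uncertainty propagation

Input uncertainty is described by triangular distributions: when only
the mean and extremes of reported measurements are available, the mean
becomes the mode and the extremes the bounds. Sampling uses the
inverse-CDF (piecewise square-root) transform; degenerate widths
collapse to point values. Monte Carlo simulation (default 10,000
iterations) propagates these distributions through the burden chain.

Design choices that matter for interpretation:

* **Shared source water.** Within an iteration, one concentration draw
  per chemical is shared across all evaluated systems — the systems
  treat the same water — while removal draws are independent per train
  and unit. This makes per-iteration differencing between systems
  well-defined, and is the basis of the paired benefit statistic (the
  fraction of iterations in which the alternative system strictly
  reduces the burden). Fully independent runs can be obtained by
  calling `run_mc()` separately per train with different seeds.
* **Sub-stream RNG.** Every sampled quantity draws from a named
  sub-stream whose seed is the global seed combined with a label hash
  (a polynomial string hash modulo $2^{31}-1$, applied to labels such
  as `cs/<chemical>` or `r/<train>/<unit>/<chemical>`). Runs are
  bit-reproducible, and adding a chemical or unit does not perturb any
  other draw.
* **Summaries.** Central tendency is reported as the median with the
  5th/95th percentiles for variability; the mean with a 95% percentile
  interval (2.5th–97.5th of the simulated distribution) for
  uncertainty. Quantiles use type-7 linear interpolation between order
  statistics — stated here because the convention is otherwise
  ambiguous. A percentile interval, not a standard-error interval of
  the mean, is the default because the interval describes simulation
  outcomes.
* **Compliance.** The compliance fraction is the percentage of
  iterations with total burden at or *below* the threshold — the
  comparison is inclusive.
* **Convergence.** `convergence_check()` re-runs a configuration under
  a different seed and reports the maximum relative deviation across
  median/p5/p95/mean; the default pass tolerance is 5%. Two runs with
  the same seed are rejected (they would trivially agree).

## Sensitivity analysis

Two complementary views are provided. Spearman rank correlation
(`mc_sensitivity()`) relates every recorded input draw to the endpoint
totals across iterations; it is tie-aware (average ranks) and invariant
under monotone transforms, so it captures the monotone chain structure
without assuming linearity. One-factor-at-a-time coefficients
(`oat_sensitivity()`) perturb an input by ±20% and report the ratio of
relative output change to relative input change for each direction;
because the single-number convention is ambiguous, both one-sided
coefficients and their mean are returned, with the mean as the headline
value (for a power law $y = x^k$ the mean tends to $k$ as the
perturbation shrinks).

## Life-cycle impact engine

The impact module is a generic, data-driven characterization engine:
$score_c = \sum_f amount_f \times factor_{f,c}$ over 10 midpoint
categories, with electricity-mix resolution (aggregate kWh split into
source-resolved flows by country shares, preserving total energy) and
mitigation scenarios (membrane-life extension scales the replacement
flow inversely; energy recovery scales electricity by
$1 - s_{hp} \times \eta$, where $s_{hp}$ is the high-pressure-pump
share of electricity, about 0.5 for a reverse-osmosis plant, and
$\eta$ the recovery efficiency, which must be supplied by the user;
transport flows can be moved between modes). No licensed
characterization factors are bundled — `generate_lci_fixture()` builds
clearly synthetic factors with a planted, known ordering of electricity
sources, sufficient to test every identity of the engine (additivity,
linearity in mixes, exact scenario scaling). Facility construction and
decommissioning are excluded, and transport is excluded from
cross-system comparisons by default though available to the mode-swap
scenario.

## What the synthetic generator does and does not emulate

`generate_cec_dataset()` reproduces the *structure* of a realistic
screening dataset: 93 chemicals in the six-category composition
41/19/17/7/5/4, concentration modes log-uniform over 1–1000 ng/L,
effect factors log-uniform over $10^{-3}$–$10^{1.1}$ cases/kg with DBPs
drawn from the top 30% of that range (DBPs are disproportionately
potent carcinogens), triangular spreads of ±50% around each mode,
technology-typical removal ranges per unit (e.g. reverse osmosis
0.90–0.99, sedimentation 0.05–0.20), 5% missing removal entries and
10% detection-limit-censored concentrations. Non-cancer effect factors
are always present; cancer factors are present with probability 0.7
(always for DBPs), reflecting that carcinogenicity data are the
scarcer resource.

It does **not** emulate real inter-chemical correlation (all draws are
independent), seasonal or spatial variability, heavy-tailed occurrence
beyond the log-uniform span, or any particular monitoring campaign's
values. Passing tests therefore demonstrate the correctness of the
computational chain and the statistical behaviour of the estimators —
not the magnitude of burdens in any real system. Real analyses should
transcribe measured concentration, removal and toxicity tables into the
documented CSV schema.

`generate_two_system_benchmark()` is deliberately artificial: unit
removal ranges are chosen so that every possible residual fraction of
the 6-unit membrane train lies strictly below every possible residual
fraction of the 7-unit conventional train. With shared source-water
draws this guarantees per-iteration dominance (paired benefit 100%),
and triangular means give closed-form expected totals — both used as
ground truth in recovery tests.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: point distributions make the
Monte Carlo exactly reproduce the deterministic chain (asserted to
1e-12 relative error); zero-width triangulars collapse to points;
constant inputs make Spearman correlations undefined and they are
returned as `NA` rather than a number. The test suite runs the full
93-chemical configuration at reduced iteration counts and the benchmark
recovery at 10,000 iterations; the acceptance script
(`scripts/acceptance.R`) uses 10,000 iterations throughout, matching
the default analysis configuration, and one-million-draw moment checks
for the triangular sampler. These sizes keep estimator noise well below
the assertion tolerances (3 Monte Carlo standard errors for recovery
checks, binomial 3σ for rate checks).

## Known limitations

* Ingestion-only exposure; no multimedia fate modelling.
* Triangular (or uniform/point) input distributions only; no
  distribution fitting from raw measurement series.
* Mixture conventions ignore toxicokinetic interaction; "additive" here
  is concentration-independent response addition over burdens.
* The impact engine is midpoint-only and carries no uncertainty
  propagation through characterization factors.
* Category-mean imputation assumes chemicals of a category behave
  alike in a unit; with sparse categories this is a strong assumption,
  which is why imputed rows are flagged.
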