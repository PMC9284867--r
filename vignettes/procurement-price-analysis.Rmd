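---
title: "Procurement price analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Procurement price analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmaproc)
library(dplyr)
```

## The problem

Public procurement registries record, purchase by purchase, who bought which
medicine, when, how many units and at what nominal unit price. Different
classes of public buyer — in the setting this package emulates: Ministry of
Education university hospitals (`ME`), the Ministry of Health (`MH`), the
Ministry of Defense (`MD`) and "Other Institutions" (`OI`, mostly state and
municipal health authorities) — routinely pay very different prices for the
same product in the same year. The pipeline quantifies that dispersion and
its cost: the *avoidable expenditure* a buyer incurred relative to the
year's cheapest public buyer, and the additional quantity that money would
have bought.

## Model and procedure

Let a stratum be a medicine × calendar year × purchaser category cell, and
let purchase *i* in a stratum have quantity $q_i$ dispensing units, nominal
unit price $p_i$ and purchase month $m_i$.

**Deflation.** Nominal prices are made comparable across a multi-year window
by a monthly consumer-price-index series $I$:
$p_i^\* = p_i \, I(r)/I(m_i)$ for a reference month $r$. Deflation commutes
with aggregation (deflate-then-sum equals sum-by-month-then-deflate) and
composes across reference months; both properties are tested. When only
annual index variations are available, `expand_annual_index()` produces a
step-wise monthly series constant within each year — this mirrors practice
where analysts deflate with annual index factors, and it makes the monthly
series the single input format.

**mg standardisation.** Several of the injectables concerned have no WHO
defined daily dose, so volume is standardised to mg of active ingredient,
$v_i = q_i \cdot \text{strength}$, and all prices are per mg.

**Weighted average price per mg.** For stratum $s$,
$\mathrm{WAP}_s = \sum_{i\in s} q_i p_i^\* \big/ \sum_{i\in s} v_i$ — the
expenditure-weighted mean price, not the mean of prices. It therefore always
lies between the cheapest and dearest sub-stratum WAP (tested as the
weighted-mean bound property), and `wap_per_mg * volume_mg` reconstructs
expenditure exactly.

**Lowest-price counterfactual.** For medicine $m$ and year $y$ the benchmark
is $B_{my} = \min_c \mathrm{WAP}_{myc}$ over categories with positive
volume, attained by the *benchmark category*. The counterfactual spend of
category $c$ is its actual spend rescaled to the benchmark price,
$\mathrm{spend}\cdot B/\mathrm{WAP}$ (equivalently $v \cdot B$), and

$$\mathrm{avoidable}_{myc} = \mathrm{spend}_{myc} - \mathrm{counterfactual}_{myc} \ge 0 .$$

One verbal description of this computation in circulation divides spending
by the lowest WAP/mg and multiplies by the actual WAP/mg, which would make
the "hypothetical" spend *larger* than the actual and the difference
non-positive; the package implements the economically coherent direction,
which also reproduces the signs and totals of the published tables it ships
as fixtures. The benchmark category's own cell is reported `NA` (its
avoidable expenditure is nil by construction), and totals sum non-`NA` cells
only. Additional purchasable quantity is
$\mathrm{avoidable}/B$ mg, converted to dispensing units by the strength and
rounded half-away-from-zero; whether published unit counts were rounded or
truncated is not documented, so half-away rounding was chosen and a ±1-unit
slack is carried in reconciliation.

**Pattern classification.** The qualitative dichotomy between a *market*
trajectory (annual volume and price inversely related) and an *inelastic*
one is made operational with the rank correlation $\rho$ between annual
volume and annual WAP/mg over years with positive volume: `market` when
$\rho \le -0.5$, `inelastic` when $|\rho| < 0.3$, `indeterminate` between,
and `insufficient_data` below 4 usable years. The source dichotomy is
visual, not quantitative; the thresholds are package choices, exposed in
`study_config()`, and should be read as a reproducible surrogate rather
than an econometric elasticity estimate. With only 7 annual points the
classifier is noisy: under exact enumeration of all $7!$ rank orderings, an
independent (continuous) volume–price pair lands in the inelastic band
50.2% of the time and in the market band 13.3% — the tests check the
Monte-Carlo label rates against these enumerated values. A zero-variance
price series is assigned $\rho = 0$: literal price constancy is the
paradigm case of inelasticity.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_start`, `window_end` | 2013-01 … 2019-12 | study window (month resolution; day-of-month is never used) |
| `min_years_purchased` | 5 | inclusion rule: distinct years with ≥ 1 qualifying purchase |
| `inclusion_category` | `MH` | category whose purchases drive inclusion |
| `reference_month` | 2019-07 | deflation target |
| `pattern_market_threshold` | −0.5 | ρ at or below ⇒ `market` |
| `pattern_inelastic_threshold` | 0.3 | \|ρ\| below ⇒ `inelastic` |
| `pattern_min_years` | 4 | usable years needed to classify |

The inclusion rule counts *distinct calendar years*, not purchase events,
and is therefore monotone in `min_years_purchased`. It is applied *after*
the active/competitive eligibility filter; the alternative order is not
documented in the source setting, and applying it after filtering means
inclusion reflects the same purchases that are analysed. The reference
month warrants a note: the study emulated here states adjustment to July
2019 in its methods but December 2019 in its figure footnotes; the package
does not resolve that ambiguity — the month is configuration, defaults to
2019-07, and is echoed in every manifest.

## The synthetic generator

`simulate_ledger()` emulates a multi-year, multi-buyer registry extract.
Unit price is
$\text{strength} \times \text{base price/mg} \times \lambda_c \times
(1+r_m)^{\Delta m} \times \varepsilon$, with category multipliers
$\lambda_c \ge 1$ (minimum exactly 1, so the $\lambda = 1$ category is the
benchmark everywhere), geometric monthly inflation $r_m$, and multiplicative
log-normal noise $\varepsilon$ with mean 1 and coefficient of variation
`price_noise_cv`; prices are positive and right-skewed, which the log-normal
respects. Annual volumes are spread uniformly over the year's months with
the remainder to the earliest months — a deterministic choice that keeps a
fixed seed byte-reproducible. The generated index series follows the same
geometric drift, so deflation cancels inflation exactly and every downstream
quantity has a closed form (returned as the `truth` table): deflated
$\mathrm{WAP}_{mc} = \text{base} \cdot \lambda_c \cdot (1+r_m)^{\Delta r}$
and avoidable expenditure $v\,\text{base}\,(\lambda_c - 1)(1+r_m)^{\Delta r}$.

Default conditions mirror the emulated study: a 7-year window, four
categories with `ME` dominating volumes (45%) and `MH` the cheapest buyer
($\lambda$ = 1.1, 1, 1.5, 1.25 for ME, MH, MD, OI — dearest in `MD`, as
observed), 0.5%/month inflation (≈ 6.2%/year, a realistic Brazilian IPCA
magnitude for the period), 10% price noise, 15% contamination with inactive
or non-competitively procured rows, and six medicines of which exactly four
pass the 5-of-7 inclusion rule. `rows_per_month` splits each monthly
allocation across that many entities; the recovery tests use 17 (204
purchases per stratum-year) so that noise averaging brings recovered
avoidable expenditure within 3% of truth at `cv = 0.1` — per *stratum* the
propagated noise at $\lambda = 1.2$ is ~5%, so the 3% claim holds at the
category and grand-total level, which is what the tests assert.

What the generator does **not** emulate: demand response to price (volumes
are exogenous), entity-level heterogeneity beyond the category multiplier,
judicialized or emergency purchases, partial-year medicine launches, and
price regulation events. Passing the recovery suite therefore shows the
pipeline's arithmetic is faithful, not that real registries satisfy the
generator's assumptions.

## Numerical choices and degenerate inputs

* Displayed percentages and unit counts round **half away from zero**
  (`round_half_away()`); base R's banker's rounding would disagree with
  published tables on exact halves. Shares are computed on full-precision
  aggregates and rounded only for display.
* Benchmark ties at full floating precision are broken by the fixed
  category order ME < MH < MD < OI, with a warning — outputs must be
  deterministic.
* Strata with zero volume are omitted from aggregation; a medicine × year
  with no purchasing category has no benchmark and is skipped.
* Currency is an opaque unit; CSVs carry plain decimals, no locale
  formatting, which is what makes repeated runs byte-identical.
* The reconciliation fixtures ship cells rounded to whole currency
  units/units as published; sums therefore match published totals only to a
  small slack (±2 is carried for monetary sums; across ~200 rounded unit
  cells the drift reaches 3–5 units in 10⁷, which the reconciliation tests
  surface rather than hide).

## Problem sizes

The test and reconciliation suites run on ledgers of roughly 2,000–11,500
rows and on the 280-cell fixture grid; the full suite completes in well
under a minute on a single CPU. These sizes were chosen as the smallest at
which the statistical claims (noise recovery at 200 purchases/stratum,
Monte-Carlo label rates over 500 replicates) are meaningful.

## Limitations

The pipeline analyses *recorded competitive purchases only*: no
deduplication across entities, no currency conversion, no cross-year
benchmarks (a benchmark is always within-year, so secular price falls are
not counted as avoidable), and no causal claim — avoidable expenditure is an
accounting counterfactual, not an estimate of what procurement reform would
save, since the benchmark price might not have been offered at the laggard
buyers' volumes or locations.
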