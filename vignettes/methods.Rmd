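---
title: "Methods: composite blending, serving removal, and isocaloric renormalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite blending, serving removal, and isocaloric renormalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmod)
```

## The model and its assumptions

dietmod implements a menu-modeling procedure: quantify the nutritional
consequence of removing one 3 oz (85 g) serving of a meat or poultry
*composite* from a 2000 kcal Healthy Dietary Pattern (the Healthy
U.S.-Style Pattern, USP, whose published baseline energy is 2001 kcal,
and the Healthy Mediterranean-Style Pattern, MSP, 2085 kcal).

The procedure makes three structural assumptions worth keeping in view:

1. **A composite stands for its food group.** Each group is reduced to
   one or two representative foods per category, blended by
   population-weighted consumption shares. Results are conditional on
   that selection; swapping representatives changes the answer.
2. **Removal is linear.** Nutrients of the serving are subtracted
   elementwise from the pattern's daily totals; no substitution behavior
   is modeled. This estimates the *maximum* effect of removal, not a
   behavioral response.
3. **Isocaloric compensation is proportional.** The isocaloric scenario
   scales every remaining food up uniformly to restore the baseline
   calorie level:
   `iso_n = (b_n − c_n) / (b_e − c_e) × b_e`.
   Equivalently `iso_n = m_n × b_e / m_e` where `m` is the modified
   (post-removal) vector; the package verifies this algebraic identity to
   1e-12 in tests, and sets the energy row to the baseline exactly.

A nutrient change of **10% or more from baseline** — inclusive, on the
absolute value of the unrounded change — marks a "meaningful
difference". Attenuation is a theorem, not an observation: whenever a
nutrient's share removed exceeds the energy share removed, the isocaloric
change is strictly smaller in magnitude than the plain-removal change
(tested as a property across all packaged scenarios).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| serving `grams` | 85 | g | the 3 oz serving all composites are profiled at |
| serving `servings` | 1 | — | removal scales linearly in servings × grams/85 |
| `threshold_pct` | 10 | % | the published meaningful-difference rule; inclusive |
| flag `basis` | unrounded | — | flags from full-precision changes; display rounding never feeds back |
| `flag_energy` | FALSE | — | energy changes are reported but not starred (always <10% here; the isocaloric column restores energy exactly) |
| `min_age` | 2 | years | inclusive age filter for proportion estimation ("age 2+") |
| proportion `tol` | 1e-6 | — | sum-to-one invariant; 1e-3 + renormalization for specs transcribed from 4-decimal printed tables |

## Numerical choices

* **Missing is explicit and propagating.** The USDA meat composite has
  no folate value; every downstream folate cell is `NA` ("not
  evaluable"), never 0. An opt-in `treat_missing_as_zero` exists for
  blending only.
* **Full precision inside, rounding at the edge.** All arithmetic is
  double precision; `round_display()` applies round-half-away-from-zero
  (matching essentially all printed cells, unlike R's banker's
  `round()`), keeps trailing zeros, and normalizes signed zero.
* **Threshold float guard.** Changes that are exactly −10% in exact
  arithmetic (baseline 1.8, removal 0.18) land at −9.9999999999999964%
  in binary; the flag comparison subtracts 1e-9 from the threshold so the
  inclusive rule behaves as stated. The guard is nine orders of magnitude
  below any scientifically meaningful difference in this setting.
* **Half boundaries.** A removal like 23 − 8.55 = 14.45 sits on a
  rounding half; IEEE subtraction can land on either side (here
  14.449999…, printing 14.4 as published; 25 − 8.55 lands at 16.450000…,
  printing 16.5 where the source prints 16.4). One documented boundary
  cell is excluded from the exact-match oracle; remaining half-boundary
  cells simply count as non-exact (the exact-match rate clears its bar
  without excluding them) and are always within one last-digit unit.
* **Degenerate inputs.** Removing a serving with energy at or above the
  baseline is an error ("infeasible removal"); a negative modeled amount
  in any other nutrient warns and is reported, not clamped — transparency
  over silent correction. Zero baselines make percent change undefined
  (error), and zero or missing energy makes density undefined (error).

## What the synthetic generator emulates — and what it does not

`generate_intake_records()` emulates the *schema and first moments* of a
dietary-recall survey: one log-normal survey weight per participant
(median 25,000 — weights that sum to a national population), uniform ages
0–80 so the inclusive age-2 filter has teeth, a Poisson number of
consumption records per participant (mean 2), log-normal consumed grams
centred on an 85 g serving, and category choice with probabilities equal
to the configured true shares. Because weights, grams and ages are drawn
independently of the category choice, the expected weighted-grams share
of each category equals the truth — which is exactly the estimand of
`estimate_proportions()`, so parameter-recovery tests are well-posed.

`generate_profiles()` emulates per-food nutrient tables at lean-meat
scale (30% CV log-normal around fixed means) with energy tied to the
4/4/9 kcal Atwater rule within ±10% wobble, and optional missingness in
micronutrients only.

Not emulated: survey design (strata/PSUs, design-consistent variance),
day-2 recall averaging, dietary-specific weight construction, FNDDS
recipe disaggregation, correlated food co-consumption, and any real
nutrient covariance structure. A green recovery test therefore
establishes that the estimator recovers weighted-consumption shares from
records of this shape — not that it reproduces published proportions
from real survey files, which are out of scope.

## Design choices where the design was open

* **Weighted consumption = Σ weight × grams** (total weighted grams),
  not a weighted count of consumers — amount-weighting is the natural
  reading and only proportions are needed downstream.
* **The within-category shares that sum to 0.9999 in print** (the
  further-processed-poultry chicken/turkey category) are accepted at a
  1e-3 tolerance and renormalized on load, so blending stays exactly
  convex; the constructor default remains 1e-6.
* **Published tables are the fixtures' ground truth.** Profiles are
  stored at printed precision, not re-derived from the underlying
  databases; whether the source computed per-100 g then scaled, or
  per-85 g directly, cannot be distinguished from print and last-digit
  drift in either direction is tolerated by the ±1-last-digit oracle.
* **Flag discrepancy policy.** Eight printed asterisks (or absences)
  cannot be recomputed from the printed inputs at the 10% rule — e.g. a
  star on a −9.52% potassium change, a missing star on a −11.31% protein
  change (a print typo by the source's own narrative), and sub-threshold
  stars on isocaloric vitamin A/C cells (+9.4 to +9.8%). These trace to
  the unrounded spreadsheet baselines behind the integer-printed pattern
  baselines. The package reproduces the printed *values*, computes flags
  honestly from its inputs, and emits every mismatch in
  `reproduce_paper()$flag_discrepancies` rather than forcing agreement;
  a regression test pins the exact discrepancy set.
* **Monotone-recovery ladder** uses the mean max-error over three fixed
  seeds at each n ∈ {200, 2000, 20000}: a single-seed ladder makes a
  stochastic ordering claim a coin flip can falsify.
* **Interfaces are JSON + CSV.** No TOML reader ships with the R
  dependency set used here, so everywhere the contract offers JSON or
  TOML, JSON is implemented.

## Known limitations

* Scope is single-composite removal from a fixed baseline: no
  replacement foods, no multi-food simultaneous removals, no adequacy
  scoring against dietary reference intakes.
* The vegetarian pattern, pattern construction itself, and real
  NHANES/FNDDS ingestion (XPT files, recall averaging) are out of scope.
* Flags and values are only as good as printed inputs; the
  discrepancy report is the honest boundary of what printed precision
  supports.

```{r example}
pats <- load_fixture("pattern_baselines")
comps <- load_fixture("table2_composites")
run_scenario(pats$MSP, comps$min_poultry)
```
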