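---
title: "Quantifying temporal variability in routinely collected health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal variability in routinely collected health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrdrift)
```

## The problem

Routinely collected EHR data are shaped as much by the recording process as
by the underlying population. Pay-for-performance schemes change what gets
coded; coding-guidance updates move diagnoses between neighbouring codes at
financial-year boundaries; practices drop out of a database and change its
demographic mix. An analysis that pools fifteen years of such data inherits
all of these shifts. `ehrdrift` measures, visualises and flags them without
requiring any prior specification of *when* a change might have happened.

## The model

Let the study window be consecutive calendar months $1, \dots, T$ and let
$P_i$ be the empirical joint distribution of the declared categorical
variables in month $i$ (the *data temporal map*, estimated as the joint
histogram divided by the monthly total). Temporal variability is the
structure of the pairwise dissimilarities

$$ D_{ij} = \mathrm{JS}(P_i, P_j), \qquad
   \mathrm{JS}(p,q) = \tfrac12 \mathrm{KL}(p \,\|\, m) +
                      \tfrac12 \mathrm{KL}(q \,\|\, m),
   \quad m = \tfrac{p+q}{2}, $$

with $0\log 0 = 0$. With log base 2 (the package default) the divergence is
bounded by 1, and so is its square root, which satisfies the triangle
inequality and is therefore used wherever Euclidean geometry is assumed.
Classical multidimensional scaling of the distance matrix
($B = -\tfrac12 J D^2 J$, eigendecomposition, coordinates scaled by
$\sqrt{\lambda_d}$) gives each month a position whose labelled trajectory is
the information-geometric temporal (IGT) plot.

### Divergence or distance?

Month-to-month *rates* of change are conventionally quoted on the divergence
scale: a single binary trait whose prevalence moves from 1.0% to 2.2%
between two months yields $1.69 \times 10^{-3}$ bits
($1.17 \times 10^{-3}$ nats), i.e. the familiar "about $1.5 \times 10^{-3}$
JSD/month" order of magnitude, whereas the square-root scale gives a value
~25 times larger ($\approx 0.04$). Because the two conventions differ by an
order of magnitude and the literature is not always explicit, the package
never silently picks one: every matrix and series carries a `scale` label,
`pairwise_matrix()` defaults to `"distance"` (the metric that MDS needs)
and rate statistics are computed from an explicitly divergence-scale matrix.
Feeding a divergence-scale matrix to `classical_mds()` is permitted but the
clamped negative-eigenvalue mass is reported, and above 10% of the spectrum
a warning points out the probable scale mistake.

## Slicing rules and their edge cases

* Ascertainment is on the **first day of each month**; a condition flag is 1
  iff a qualifying code exists *strictly before* that day. A code dated
  2003-05-10 therefore first counts in the 2003-06 slice.
* Eligibility (primary-care mode): age 20–110 at the first of the month and
  registration started at least 365 days earlier (day-based, not
  calendar-year arithmetic; configurable). A registration that ends anywhere
  inside month $m$ still contributes to $m$.
* With year-of-birth-only data, age is `year(m) − yob` from July onward and
  one less before: every patient turns a year older in July. This
  reproduces the artificial July jumps such data are known for; an
  exact-date-of-birth mode is available when a `date_of_birth` column
  exists.
* Empty months are kept as explicit gaps: they are excluded from the
  temporal map with a warning, consecutive-month series split at the gap,
  and trajectories break rather than interpolate across it.
* ICD-10 codes are truncated to 3 characters before matching; Read-style
  codes are matched exactly. A code may belong to at most one condition
  within a codelist set.

## Detection thresholds

The package replaces visual inspection of IGT plots with three explicit
rules, all exposed as arguments:

| rule | statistic | default threshold |
|---|---|---|
| abrupt change | consecutive divergence vs `median + k·1.4826·MAD` | `k = 5` |
| gradual trend | Spearman ρ of time vs dimension-1 coordinate | `|ρ| ≥ 0.8` |
| period clusters | mean silhouette over a candidate grouping | `≥ 0.5` |

These thresholds are this package's own calibration choices. Their
justification is the null-scenario suite: on 20 seeds of a no-effect
hospital scenario (50 000 codes/month, 180 months), the abrupt rule fires in
no more than 5% of seeds and the trend/cluster rules in at most 5% each,
while a planted single-code step of the realistic size (8.0% → 10.9% of
monthly codes) is recovered at exactly the planted transition, with the
correct variable ranked first, in ≥ 90% of seeds. A constant series (MAD
= 0) degenerates to flagging any strictly larger value. Seasonality is
probed only as a `month_of_year` candidate grouping. Attribution recomputes
the dissimilarity at a flagged transition on each single-variable marginal
map; because marginalisation commutes with estimation, these scores are
exactly the single-variable analyses they emulate.

## The synthetic generator: a stated world

Real CPRD GOLD / HES extracts are access-controlled, so validation runs on
synthetic data whose temporal structure is *planted* and exported as a
ground-truth manifest. The generator's defaults are the conditions the
analysis is meant to face:

* **Primary-care mode** (default 200 000 patients — chosen for statistical
  stability of monthly prevalence, as no real monthly volume is public):
  four cardiovascular conditions whose recorded prevalence rises linearly
  over 2001–2007 (CHD 44.7→48.2, heart failure 6.7→10.8, PAD 7.0→10.3,
  stroke 14.4→23.4 per 1000 patients) in `scenario_cprd_like()`.
* **Hospital mode** (default 50 000 included codes/month over 180 months):
  six 3-character codes with stable shares, plus an 8.0% → 10.9% step in I21
  applied on the first day of the stated month (the March/April
  financial-year boundary, transition index 135) in `scenario_hes_like()`.
  A remainder pseudo-code `"OTH"` absorbs unallocated share so monthly
  shares always normalise; each month's counts are one multinomial draw
  over code × demographic cells.

Two design choices deserve explanation:

* **Deterministic count-matching.** Each month the primary-care generator
  converts exactly `round(target·n_eligible) − n_affected` unaffected
  eligible patients (chosen uniformly at random, dated in the previous
  month). Realised prevalence therefore tracks the target up to rounding,
  which is what the stochastic checks (e.g. a realised +62.5% stroke rise
  within ±5 points) assume. A per-patient Bernoulli-hazard formulation
  would add binomial wander around the trajectory without making the world
  more realistic in any dimension the pipeline measures.
* **Declines require churn.** An ever-recorded phenotype is monotone within
  a patient, so recorded prevalence can only fall in an open cohort when
  leavers are replaced by entrants with lower recorded prevalence. A
  decreasing trajectory with `churn_rate = 0` is rejected with an
  explanatory error; with churn, entrants are seeded at
  `entry_prevalence_factor` times the target, and dropout schedules
  (optionally biased towards particular deprivation quintiles) emulate
  selective practice attrition and its population-mix shift.

All randomness flows from one integer seed through a linear-congruential
splitting scheme keyed by (stream, month index, condition index), so output
is byte-identical across runs and sub-streams are stable when unrelated
parts of a scenario change.

What the generator deliberately does **not** emulate: comorbidity
correlation between conditions (flags are planted independently),
correlation between codes and demography in hospital mode (cell
probabilities are products, which is also what makes the
marginal-invariance oracle exact), free-text, drug data, and multi-practice
hierarchies beyond the dropout schedule. A green pipeline test therefore
establishes that the machinery recovers planted effects of realistic size
under multinomial/registration noise — not that real CPRD/HES data would
show these effects, nor that effects entangled with correlated demography
would attribute as cleanly.

## Numerical choices

* Probability vectors must sum to 1 within `1e-9`; matrices are symmetric by
  construction and checked to `1e-12` on input.
* The temporal-map support is the union of observed category combinations,
  ordered lexicographically by variable order then category order, fixed at
  construction — deterministic serialisation and plotting. No smoothing is
  applied (all variables are categorical), so counts are exactly
  recoverable as `probabilities × denominators`; a smoothing hook would sit
  between counting and normalisation but is deliberately absent.
* MDS eigenvalue ties and the arbitrary axis sign are resolved by ordering
  on (eigenvalue, dimension index) and flipping each dimension so its
  largest-magnitude coordinate is positive; tests compare distances or use
  alignment, never raw coordinates.
* Percent changes round half-away-from-zero (36.25 → 36.3 at 1 dp), with a
  few-ulp guard so exact decimal ties whose binary representation falls a
  hair below .5 still round away from zero. Relative change is undefined
  (and rejected) for a zero baseline.
* Trajectory knots are interpolated linearly in *month index*, not in days,
  so equal monthly increments between knots survive unequal month lengths.

## Interfaces

The package is function-first, in the tradition of analysis packages whose
users work from R: generators → slicers → `estimate_dtm()` →
`pairwise_matrix()` → `classical_mds()`/detectors, with delimited-text
readers and writers (`read_patients()`, `read_counts()`, `read_codelist()`,
`write_table_csv()`) for every table schema, and `scripts/acceptance.R` as
the scripted entry point. Exports (`dtm_heatmap()`, `igt_export()`) are
text-first; images are a thin optional layer over the exported matrices.

## Known limitations

* Kernel-density temporal maps for continuous variables are out of scope;
  all variables must be categorical (or categorised upstream).
* The joint support is dense; ~4 000 columns (8 age bands × 2 genders × 5
  quintiles × ~50 codes) is by design the intended ceiling.
* Silhouette-based cluster detection compares a group against the *nearest*
  other group, so period groupings in which non-adjacent periods return to
  an earlier regime (A-B-A patterns) score near zero even when regimes are
  well separated; such patterns still surface through the abrupt-change
  rule at each boundary.
* Detection thresholds are calibrated on the synthetic null above; datasets
  with much smaller monthly volumes have a higher sampling-noise floor, and
  `k`, `rho_threshold` and `silhouette_threshold` may need revisiting.
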