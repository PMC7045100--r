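# ehrdrift

Temporal variability analysis of routinely collected electronic health
records (EHR).

Longitudinal EHR databases pool data recorded by many clinicians over many
years. How conditions are *coded* changes over that time — incentive schemes,
coding-guidance updates, software migrations and practice dropout all leave
fingerprints in the data that have nothing to do with patients getting
sicker or healthier. Studies that pool years of records without checking for
such shifts risk biased phenotypes and spurious trends. `ehrdrift` is for
epidemiologists and health-data scientists who want a data-driven,
assumption-light screen for these effects before committing to an analysis.

## Method

The pipeline follows the information-geometric temporal (IGT) approach to
dataset-shift assessment:

1. **Monthly slicing.** Records are divided into monthly cross-sectional
   slices. For primary-care-style data, a patient contributes to month *m*
   if aged 20–110 on the first of the month and registered for ≥ 1 year;
   conditions are ever-recorded flags (any qualifying code strictly before
   the month). For hospital-style data, pre-aggregated counts of included
   3-character ICD-10 codes are used directly.
2. **Data temporal map (DTM).** Each month *i* is summarised by its
   empirical joint distribution `P_i` over the categorical variables (age
   band × gender × deprivation quintile × condition flags or code): the
   joint histogram divided by the monthly total.
3. **Jensen–Shannon dissimilarity.** Months are compared pairwise with
   `JS(p, q) = ½ KL(p‖m) + ½ KL(q‖m)`, `m = (p+q)/2`. With log base 2 both
   the divergence and its square root (a metric, the Jensen–Shannon
   *distance*) lie in [0, 1]: 0 for equal distributions, 1 for disjoint
   support. Both scales are exposed and labelled.
4. **IGT embedding.** Classical multidimensional scaling (Torgerson double
   centering, `B = −½ J D² J`) of the month × month distance matrix embeds
   each month in 2–3 Euclidean dimensions; the labelled trajectory is read
   for gradual trends, abrupt breaks, period clusters and outliers.
5. **Detection and attribution.** Control-chart rules replace visual
   inspection: consecutive-month dissimilarities beyond
   `median + 5 × 1.4826 × MAD` flag abrupt changes; Spearman |ρ| ≥ 0.8
   between time and the leading coordinate flags trends; a mean silhouette
   ≥ 0.5 over candidate period groupings (calendar year, NHS financial
   year, month-of-year) flags clustering. Flags are attributed to variables
   by recomputing the dissimilarity on each single-variable marginal map.

A synthetic cohort generator plants known drifts, step changes, population
mix shifts and practice dropout in CPRD-GOLD-like and HES-like data, so the
whole pipeline can be validated against ground truth.

## Worked example

Fifteen years of hospital-style counts (50 000 coded admissions/month), with
the acute-myocardial-infarction code I21 stepping from 8.0% to 10.9% of
included codes at the March/April 2012 financial-year boundary (transition
index 135):

```r
library(ehrdrift)

sc     <- scenario_hes_like(monthly_volume = 50000, n_months = 180,
                            step_index = 135, seed = 7)
gen    <- generate_hospital_counts(sc)
slices <- build_hospital_slices(gen$counts, unique(gen$counts$code),
                                sort(unique(gen$counts$month)))
dtm    <- estimate_dtm(slices)

series <- consecutive_series(pairwise_matrix(dtm, scale = "divergence"))
flags  <- detect_abrupt(series)
flags
#>     type step_index       from         to       value    score
#> 1 abrupt        135 2012-03-01 2012-04-01 0.005914195 7.562545

attribute_source(dtm, flags$step_index[1])
#>       variable        score rank
#> 1         code 2.070183e-03    1
#> 2     age_band 6.728580e-05    2
#> 3 imd_quintile 1.026946e-05    3
#> 4       gender 9.706622e-07    4

code <- marginalize(dtm, "code")
i21  <- code$probabilities[, code$support$code == "I21"]
relative_change(i21[135], i21[136], 0)
#> [1] 37
```

The one flagged transition is exactly the planted March→April 2012 boundary;
its robust z-score (7.6) is far above the k = 5 control limit while no other
month fires. Attribution ranks `code` two orders of magnitude above the
demographic variables — the change is a coding change, not a population
change — and the realised I21 share moves by +37% (target +36%, multinomial
sampling noise accounts for the difference). For visual inspection,
`classical_mds()` on the distance-scale matrix gives the IGT embedding
(here 16.9% of variance on dimension 1) and `plot()` / `igt_export()` /
`dtm_heatmap()` render or export the figures.

## Acceptance script

`scripts/acceptance.R` recomputes the package's deterministic reference
quantities — the Jensen–Shannon dissimilarity for the 1.0% vs 2.2%
single-trait worked example and the identical/disjoint boundary cases — by
running the installed package, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
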