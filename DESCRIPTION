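Package: ehrdrift
Title: Temporal Variability Analysis of Routinely Collected Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies and visualises how the statistical distribution of
    routinely collected electronic health record (EHR) data changes over
    calendar time. Longitudinal primary-care-style records or preaggregated
    hospital-style counts are divided into monthly cross-sectional slices,
    summarised as data temporal maps (per-month empirical joint distributions
    over categorical variables), and compared through pairwise Jensen-Shannon
    dissimilarities. Classical multidimensional scaling of the dissimilarity
    matrix yields information-geometric temporal (IGT) plots of the data's
    evolution, and statistical-process-control style heuristics flag gradual
    trends, abrupt changes and period clusters, attributing each finding to
    the variables that drive it. A synthetic cohort generator with planted
    coding changes (prevalence drifts, step changes, population-mix shifts,
    practice dropout) supports validation of the whole pipeline against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
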