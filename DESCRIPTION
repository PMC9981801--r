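Package: glycorisk
Title: Diabetes Risk Scoring, Pedigree Genetic Coefficients and Glucose Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for population-scale diabetes risk evaluation from
    longitudinal clinical records. Aggregates timestamped indicator
    records with normalized exponential decay weights, trains a
    soft-margin linear classifier and calibrates its decision values
    into a Diabetes Index in [0,1], computes genetic coefficients over
    family pedigrees via direct lineage and most-recent common
    ancestors, forecasts ambulatory blood-glucose series with a
    restricted Boltzmann machine trained by contrastive divergence,
    and implements rule-based glycemic classifications (diagnosis
    thresholds, elderly glycemic-control targets) and descriptive
    cohort statistics. Includes a seeded synthetic-data generator for
    cohorts, pedigrees and glucose traces, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
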