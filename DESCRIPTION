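Package: accelsleep
Title: Cardiorespiratory Sleep Staging from Chest-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for estimating sleep stages from a
    chest-worn triaxial accelerometer. Localizes heartbeats in the
    seismocardiographic component of the signal, derives instantaneous
    heart rate with quality-based gap masking, estimates respiratory
    effort from slow orientation changes of the sensor, computes
    per-second activity counts, mixes activity back into the effort
    signal, and classifies 30-second epochs into Wake, N1+N2, N3 and
    REM with whole-night temporal smoothing. Includes inter-beat-interval
    based clock synchronization between independently clocked devices,
    a full hypnogram-agreement and sleep-metric evaluation battery
    (Cohen's kappa, one-vs-rest metrics, Bland-Altman limits of
    agreement, gap-tolerant stage-interval analysis, cohort factor
    statistics), and a synthetic overnight-recording generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    nnet,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Depends: R (>= 4.0)
SystemRequirements: C++11
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
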