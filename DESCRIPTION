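Package: scskinetics
Title: Double-Sigmoid Modelling of Paw Withdrawal Threshold Time Courses
    During Spinal Cord Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a five-parameter double-sigmoid response model to paw
    withdrawal threshold (PWT) time courses recorded before, during and
    after spinal cord stimulation, quantifying the wash-in and wash-out
    kinetics of stimulation-induced analgesia. Provides baseline
    normalization, summed-squared-deviation curve fitting from a fixed
    initialization, percent-deviation fit quality with exclusion rules,
    derived temporal metrics (midpoint slopes and normalized
    full-width-half-maximum), a synthetic-data generator emulating a
    five-pattern randomized crossover design with two stimulation
    durations, and the cohort-level paired comparisons used to contrast
    time-dynamic stimulation patterns against tonic stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    lmerTest,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
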