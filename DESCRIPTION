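Package: qtdecay
Title: Model-Based QT Interval Estimation for Fetal Mouse Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fetal-mouse QT intervals from RR intervals alone using an
    exponential repolarization-decay model in which the end of the T wave is the
    median of the times where the decay curve crosses a rate-dependent threshold
    band. T waves are commonly unmeasurable in fetal mouse electrocardiograms, so
    the package also provides automatic R/Q fiducial detection, cross-system
    clock alignment via shared marker pulses, Q-to-aortic-closure interval
    computation from Doppler event timestamps, and the agreement statistics
    (Bland-Altman limits, correlation, difference percentages) used to validate
    the model against Doppler ultrasound. A synthetic co-registered
    fECG/Doppler generator with known ground truth makes the whole workflow
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
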