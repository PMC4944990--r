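Package: dyadsync
Title: Social Psychophysiological Compliance from Dyadic Heart-Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify interpersonal physiological synchrony
    ("social psychophysiological compliance") between collaborating dyads
    from single-channel electrocardiography. Provides R-peak detection and
    artifact-filtered normal-to-normal interbeat-interval series, sliding
    window time-domain heart-rate-variability features (heart rate, SDNN,
    rMSSD), within-dyad Pearson compliance with a class-restricted
    permutation test of its classroom mean, step-down multiplicity
    correction, and a linear model relating compliance to summed NASA-TLX
    style self-reports. A synthetic classroom generator produces coupled
    dyadic beat series, optional ECG waveforms, and self-reports with
    known ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
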