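Package: mechanospike
Title: Neuromorphic Tactile Encoding, Temporal Spike Coding and
    Peripheral-Nerve Recruitment Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a sensorized artificial fingertip sliding over ridged
    gratings, converts the two-channel piezoresistive signal into spike
    trains through an Izhikevich artificial mechanoreceptor
    (mechano-neuro-transduction), and analyses the resulting temporal code:
    burst segmentation, inter-burst intervals (IBI), average firing rates
    (AFR), spatial modulation indices, and the regressions and ANOVA
    contrasts that separate interval-based from rate-based texture codes.
    Includes a three-alternative forced-choice psychophysical protocol with
    an ideal-observer decoder, exact Clopper-Pearson intervals and logistic
    psychometric fits, and a desk-scale hybrid model of peripheral-nerve
    microstimulation: analytic anisotropic volume conductor, 21-node
    myelinated-axon model with active nodes of Ranvier, fiber-population
    recruitment curves, and the needle-versus-intrafascicular-electrode
    equivalence test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix
Config/testthat/edition: 3
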