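Package: spikebench
Title: Benchmarking Spike Encoding of Time-Varying Signals with Spiking Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for converting time-varying sensor signals (audio,
    inertial) into the event domain and benchmarking the conversion on a
    neuromorphic classification task. Provides cochlea-inspired gammatone and
    Butterworth filter banks, eleven rate- and temporal-coding spike encoders
    (Poisson rate, threshold-based representation, moving window, step-forward,
    zero-crossing step-forward, Hough spiker, modified Hough spiker, Ben's
    spiker, phase, time-to-first-spike, burst), sonogram feature extraction by
    time binning, a zero-bias average-pooling convolutional network trained by
    stochastic gradient descent, conversion to a leaky integrate-and-fire
    spiking twin, quantile-based synaptic pruning with masked fine-tuning,
    information-theoretic characterization of spike trains, and synthetic
    labelled corpora emulating mid-frequency audio and low-frequency inertial
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
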