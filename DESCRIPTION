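Package: corticond
Title: Simulation and Analysis of Cortical Layer-5 Population Activity
    During Pavlovian Trace Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse appetitive Pavlovian trace
    conditioning experiments with longitudinal two-photon calcium imaging
    of cortical layer-5 projection-neuron populations. Provides a
    synthetic-data generator for trial tables, licking behaviour and ROI
    fluorescence traces; behavioural scoring by anticipatory-lick auROC;
    calcium-imaging analyses (dF/F extraction, Wilcoxon responsiveness
    classification, ROC selectivity index, day-to-day stability and
    response-class transitions, population-fraction chi-squared tests,
    Ward clustering, event-triggered averaging); time-binned linear-SVM
    population decoding of stimulus identity and lick rate; and a
    Rescorla-Wagner-type two-channel value-learning network with a
    pretrained autoencoder stimulus-representation channel, reward
    prediction errors, cell-type silencing conditions and an S1-independent
    transfer sub-network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
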