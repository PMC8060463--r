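Package: sdcae
Title: Supervised Deep Convolutional Autoencoders for Seizure Detection in Multichannel EEG
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of epileptic seizures in pediatric multichannel scalp
    EEG by classifying short raw signal segments as ictal or interictal.
    Implements a supervised deep convolutional autoencoder (SDCAE) trained
    jointly on reconstruction and classification, with either a multilayer
    perceptron or a bidirectional LSTM classification head, plus matched
    decoder-free convolutional baselines.  Includes a reproducible synthetic
    EEG generator, EDF reading and writing, CHB-MIT-style seizure annotation
    parsing, balanced segment dataset construction with global z-score and
    min-max normalization, stratified 10-fold cross-validation, the five
    standard confusion-matrix metrics, and Kruskal-Wallis significance
    testing across models.  The neural-network engine (same-padded 2-D
    convolution, batch normalization, max pooling, nearest-neighbour
    upsampling, LSTM cells, dense layers, backpropagation and the Adam
    optimizer) is implemented in vectorized R and verified against
    brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
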