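Package: vqcpc
Title: Discrete Symbolic Representations of Wearable Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns strings of discrete motion symbols from windows of
    triaxial wearable accelerometer data via vector-quantized contrastive
    predictive coding (VQ-CPC): a strided convolutional encoder, grouped
    online K-means vector quantization with a straight-through gradient
    estimator, a causal convolutional aggregator trained with an InfoNCE
    future-prediction objective, and commitment/codebook losses. Includes
    the downstream token-sequence activity classifier (embedding + GRU/LSTM
    + MLP with participant-wise cross-validation and macro-F1 reporting),
    SAX and SAX-REPEAT discretization baselines, masked-token language-model
    pre-training on symbol corpora, a synthetic wrist-accelerometry
    generator for end-to-end testing, and pipeline orchestration. All
    networks are implemented in base R with hand-written backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
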