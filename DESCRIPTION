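Package: ecogdecode
Title: Sequence-to-Sequence Decoding of Sentences from ECoG High-Gamma Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes token sentences from electrocorticographic (ECoG) recordings of
    overt and covert (imagined) speech. Implements the full pipeline: high-gamma
    (70-150 Hz) envelope feature extraction at 200 Hz, a temporal-convolution front
    end, and a Transformer (or bidirectional-LSTM baseline) encoder-decoder trained
    with a dual loss (token cross-entropy plus an auxiliary MFCC regression on the
    encoder output). Includes a synthetic multichannel data generator with planted,
    condition-dependent token codes, trial-stratified cross-validated experiment
    orchestration with temporal-shuffle controls, token-error-rate scoring from a
    minimum-edit-distance alignment, paired Wilcoxon/Holm-Bonferroni statistics, and
    gradient-saliency electrode contribution maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
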