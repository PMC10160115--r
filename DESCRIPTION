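Package: stimdecode
Title: Stimulus-to-Label Alignment and Multi-Voxel Sentiment Decoding for
    Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decoding sentiment from naturalistic movie-watching
    fMRI. Parses time-stamped word annotations into sentences, scores them
    with a lexicon-based compound sentiment score (with negation handling),
    aligns per-sentence polarity labels to the fMRI volume (TR) grid using
    ceiling and gap-carry rules, extracts voxel time series from spherical
    regions of interest around MNI seed coordinates, assembles labeled
    multi-subject feature matrices, balances classes by random oversampling
    or SMOTE, and classifies sentiments with random forests, support vector
    machines, decision trees, and a multilayer perceptron, including
    shuffled-label chance controls and k-fold cross-validation. A synthetic
    data generator with known ground truth makes every stage testable
    without neuroimaging downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    rpart,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
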