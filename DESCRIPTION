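Package: termharvest
Title: Harvesting Clinical-Specialty Term Sets from Labeled Biomedical Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds interface terminologies for clinical specialties from
    specialty-labeled title/abstract corpora. Extracts word n-grams (n = 1-3)
    with rule-based cleansing against stopword and geographic gazetteers,
    weights each term with three specialty-aware measures (an entropy-derived
    global concentration measure, a local precision measure and a
    frequency-gated local relevance measure), detects and removes stop
    n-grams whose relevance profile is flat across nearly all specialties,
    and serializes the resulting per-specialty term resource. The resource
    can score documents as per-specialty feature vectors for multi-label
    specialty classification, evaluated with micro-averaged precision,
    recall and F1. A synthetic corpus generator with planted
    specialty-exclusive, shared and ubiquitous terms provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    Matrix,
    stats,
    utils,
    nnet,
    rpart,
    randomForest,
    class,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
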