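Package: ticmotion
Title: Two-Stage Contrastive Video Pipeline for Facial Tic Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and classifies motor facial tics (eye tics, mouth tics)
    in video recordings using a two-stage architecture: self-supervised
    contrastive pretraining of a convolutional visual encoder with the
    normalized temperature-scaled cross-entropy (NT-Xent) loss over
    subject-restricted minibatches of continuous frames, followed by an LSTM
    clip classifier trained with focal loss. Includes face-ROI preprocessing
    (bounding-box expansion, temporal downsampling, one-second clip
    windowing), VoTT-style annotation handling, leave-one-subject-out
    evaluation with clinical tic-severity summary items, Grad-CAM saliency
    maps, and a procedural synthetic-cohort generator with ground-truth face
    boxes so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
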