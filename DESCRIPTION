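Package: marginseg
Title: Margin-Aware Tumor Segmentation for Intraoperative Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting tumors in intraoperative B-mode ultrasound
    with an emphasis on the top (surgical) resection margin. Implements the
    generalized Dice loss and a gradient-weighted Dice loss that up-weights
    the shallow tumor boundary, a tumor-margin error metric in millimeters,
    pixel-pooled ROC/AUC evaluation, probability-map ensemble fusion
    (averaging, voting, pixel classifier) with validation-set optimization,
    morphological post-processing, a speckle phantom simulator for
    ultrasound-like test data, and a desk-scale training harness for small
    encoder-decoder segmentation networks with transfer learning via
    reduced-rate fine-tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
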