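Package: mitoseval
Title: Evaluation Workflow for Mitosis Detection in Histopathology Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the evaluation side of a mitosis-detection workflow for
    canine Perivascular Wall Tumour histology: dual-annotator centroid
    agreement statistics, tissue-aware 512x512 patch and high-powered-field
    extraction from whole-slide thumbnails, detection post-processing
    (non-maximum suppression), IoU-based greedy matching with global
    sensitivity/precision/F1, adaptive F1-score threshold selection on a
    validation split, and pathologist-in-the-loop false-positive review that
    produces versioned ground-truth datasets. A synthetic-data generator
    emulates slides, annotators and a scored object detector so the whole
    pipeline is testable without real whole-slide images or a trained model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
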