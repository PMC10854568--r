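#' Bundled reference tables from the source mitosis-detection study
#'
#' Small plain-text copies of the published result tables of the canine
#' Perivascular Wall Tumour mitosis-detection study this workflow
#' re-implements. They serve as regression fixtures: every published metric
#' is an exact function of the published counts, so the package's metric and
#' aggregation code can be checked against them without access to the
#' (unavailable) slides, annotations, or trained detector.
#'
#' * `reference_agreement_counts()` — per-slide annotation counts for the two
#'   annotators and the agreed count, over the 19 training/validation slides.
#' * `reference_detection_counts()` — per-fold (TP, FP, FN) counts with the
#'   published 3-decimal sensitivity/precision/F1, for the initial
#'   40x-vs-20x comparison and the initial-vs-updated dataset comparison.
#' * `reference_threshold_metrics()` — per-fold published metrics before and
#'   after validation-selected score thresholding (thresholds 0.96, 0.84,
#'   0.91 for folds 1-3).
#'
#' @return a data.frame (see above)
#' @name reference_tables
NULL

ref_path <- function(file) {
  system.file("extdata", file, package = "mitoseval", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
reference_agreement_counts <- function() {
  utils::read.csv(ref_path("annotator_counts.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_detection_counts <- function() {
  utils::read.csv(ref_path("detection_counts.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_threshold_metrics <- function() {
  utils::read.csv(ref_path("threshold_comparison.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(threshold = "character"))
}
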