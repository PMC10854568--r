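#!/usr/bin/env Rscript
# Tissue masking and patch extraction: Otsu masks from the thumbnails,
# 512x512 tissue patches (>= 75% tissue) for train/val slides, and the
# 4096x2560 ten-HPF region tiled into 40 patches for each hold-out test
# slide. Ground-truth boxes (32 px squares at 20x around agreed centroids)
# are assigned to patches by centre containment.
# Writes results/pipeline/patch_manifest.csv.

source(file.path("analysis", "00_config.R"))

state <- pipeline_upto("extract")

for (sid in names(state$patches)) {
  p <- state$patches[[sid]]
  g <- state$gt[[sid]]
  role <- if (sid %in% analysis_config()$test_slides$slide_id) "test" else "train/val"
  cat(sprintf("  %s (%s): %3d patches, %3d ground-truth boxes\n",
              sid, role, nrow(p), nrow(g)))
}
n_test <- sum(vapply(analysis_config()$test_slides$slide_id,
                     function(s) nrow(state$patches[[s]]), numeric(1)))
cat("Hold-out patches:", n_test, "(40 per test slide)\n")
cat("Train/val patches without mitosis were dismissed from the manifest.\n")
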