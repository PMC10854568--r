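#!/usr/bin/env Rscript
# Simulate the synthetic slide cohort: blobby tissue on glass, true mitosis
# centroids inside tissue, and two imperfect annotators per slide.
# Writes thumbnails, truth masks, truth centroids and per-annotator marks
# under results/pipeline/slides/.

source(file.path("analysis", "00_config.R"))

state <- pipeline_upto("simulate")

cat("Simulated", length(state$slides), "slides\n")
for (sid in names(state$slides)) {
  sl <- state$slides[[sid]]
  anns <- state$annotations[[sid]]
  cat(sprintf(
    "  %s: %5.1f%% tissue, %3d true mitoses, annotator marks: %d / %d\n",
    sid, 100 * mean(sl$mask$grid), nrow(sl$centroids),
    nrow(anns[[1]]), nrow(anns[[2]])))
}
cat("Artifacts in", file.path(ANALYSIS_OUT, "slides"), "\n")
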