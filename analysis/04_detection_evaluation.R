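#!/usr/bin/env Rscript
# Detection evaluation before thresholding: simulate scored detections from
# the detector model on every fold's validation slides and on the hold-out
# set, apply per-patch NMS (IoU 0.1), match to ground truth at IoU >= 0.5,
# and micro-average TP/FP/FN into global sensitivity/precision/F1 per fold.
# Writes results/pipeline/metrics_initial.csv.

source(file.path("analysis", "00_config.R"))

state <- pipeline_upto("evaluate")

m <- state$initial_metrics
m$sensitivity <- round_half_up(m$sensitivity, 3)
m$precision <- round_half_up(m$precision, 3)
m$f1 <- round_half_up(m$f1, 3)
print(m, row.names = FALSE)
cat("\nThe detector is sensitive but imprecise before thresholding:\n")
cat(sprintf("  mean test sensitivity %.3f, mean test precision %.3f\n",
            mean(m$sensitivity[m$Set == "Test"]),
            mean(m$precision[m$Set == "Test"])))
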