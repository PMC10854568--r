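# Shared configuration for the analysis scripts.
#
# One synthetic cohort stands in for the unavailable whole-slide scans: six
# training/validation slides and three hold-out test slides, two simulated
# annotators, and a simulated scored detector. Every script rebuilds the
# pipeline state it needs from this seed, so the scripts can be run in any
# order and always agree with one another.

library(mitoseval)

ANALYSIS_SEED <- 20240201L
ANALYSIS_OUT <- file.path("results", "pipeline")

analysis_config <- function() {
  pipeline_config(out_dir = ANALYSIS_OUT, seed = ANALYSIS_SEED)
}

# run the pipeline through stage `upto` (deterministic, so cheap to redo)
pipeline_upto <- function(upto) {
  all_stages <- c("simulate", "agree", "extract", "evaluate", "optimize",
                  "review")
  suppressMessages(
    run_pipeline(analysis_config(),
                 stages = all_stages[seq_len(match(upto, all_stages))]))
}
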