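#!/usr/bin/env Rscript
# Two-annotator agreement: pair each annotator's centroids within the
# agreement radius, build the per-slide agreement table (counts and
# percentages), and report the per-annotator average agreement. Writes
# results/pipeline/agreement.csv.

source(file.path("analysis", "00_config.R"))

state <- pipeline_upto("agree")

print(state$agreement$table, row.names = FALSE)
cat(sprintf("Average agreement: annotator 1 %.2f%%, annotator 2 %.2f%%\n",
            state$agreement$avg["pct_agree_anno1"],
            state$agreement$avg["pct_agree_anno2"]))
cat("Unpaired marks are dismissed; consensus positions are pair midpoints.\n")

# the same computation on the published per-slide counts, for comparison
pub <- agreement_summary(reference_agreement_counts())
cat(sprintf("Published-study counts give averages %.2f%% / %.2f%%\n",
            pub$avg[1], pub$avg[2]))
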