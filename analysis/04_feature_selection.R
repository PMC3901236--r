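#!/usr/bin/env Rscript
# Univariate biomarker screen on the targeted 19-metabolite table:
# per-metabolite Student's t-test (uncorrected) and signed fold changes,
# writing a published-marker-style summary table.

source("analysis/00_common.R")

ft <- read_feature_table(file.path(results_dir, "feature_table.tsv"))
sel <- select_features(ft, alpha = 0.05, positive = "HCC")

message(sprintf("%d of %d metabolites pass p < %.2f:",
                length(sel$selected), nrow(sel$stats), sel$alpha))
top <- sel$stats[sel$stats$feature %in% sel$selected,
                 c("feature", "p", "fold_change")]
for (i in seq_len(nrow(top))) {
  message(sprintf("  %-14s p = %8.2e  fold change %+0.2f",
                  top$feature[i], top$p[i], top$fold_change[i]))
}

write_selection_tsv(sel, file.path(results_dir, "marker_screen.tsv"),
                    lib = study_library)
write_selection_tsv(sel, file.path(results_dir, "selected_markers.tsv"),
                    lib = study_library, selected_only = TRUE)
message("screen tables -> results/marker_screen.tsv, results/selected_markers.tsv")
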