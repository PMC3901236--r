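#!/usr/bin/env Rscript
# Model validation: PCA + PLS-DA with 7-fold cross-validated ROC on the
# 19-metabolite table and on the three significant markers (valine,
# creatinine, choline), then 200-iteration Monte-Carlo cross-validation
# with a permutation null for both models, aggregated into
# publication-style confusion matrices.

source("analysis/00_common.R")

ft <- read_feature_table(file.path(results_dir, "feature_table.tsv"))
X <- ft$values
labels <- ft$labels
markers <- c("valine", "creatinine", "choline")

run_model <- function(X, tag) {
  cv <- kfold_cv_predict(X, labels, k = 7, n_lv = N_LV, positive = "HCC",
                         scale = "autoscale", seed = MCCV_SEED)
  roc <- roc_auc(cv, labels, positive = "HCC")
  message(sprintf("[%s] 7-fold cross-validated AUC: %.3f", tag, roc$auc))
  write_roc(roc, file.path(results_dir, paste0(tag, "_roc.tsv")))

  true_run <- mccv(X, labels, n_iter = N_ITER, n_lv = N_LV,
                   positive = "HCC", seed = MCCV_SEED)
  perm_run <- permutation_mccv(X, labels, n_iter = N_ITER, n_lv = N_LV,
                               positive = "HCC", seed = MCCV_SEED + 1)
  ts <- sensitivity_specificity(true_run$confusion)
  ps <- sensitivity_specificity(perm_run$confusion)
  message(sprintf("[%s] MCCV (%d iter): sens %.2f spec %.2f | permuted: sens %.2f spec %.2f",
                  tag, N_ITER, ts[1], ts[2], ps[1], ps[2]))

  tab <- format_confusion_table(true_run, perm_run, negative = "HCV")
  con <- file.path(results_dir, paste0(tag, "_confusion.txt"))
  writeLines(c(sprintf("MCCV confusion matrix, %d iterations (permutation in parentheses)", N_ITER),
               capture.output(print(tab, quote = FALSE))), con)
  write_mccv_json(true_run, perm_run,
                  file.path(results_dir, paste0(tag, "_mccv.json")),
                  extra = list(model = tag, features = colnames(X)))
  invisible(list(true = true_run, perm = perm_run, roc = roc))
}

# PCA overviews (scores written for plotting elsewhere)
for (set in list(list(X, "model19"), list(X[, markers], "model3"))) {
  p <- fit_pca(autoscale(feature_table(set[[1]], labels = labels))$values,
               n_comp = 2, center = FALSE)
  sc <- data.frame(sample_id = rownames(X), label = labels, p$scores)
  colnames(sc)[3:4] <- c("PC1", "PC2")
  utils::write.table(sc, file.path(results_dir, paste0(set[[2]], "_pca_scores.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("[%s] PCA: PC1 %.1f%%, PC2 %.1f%% of variance", set[[2]],
                  100 * p$explained_variance[1], 100 * p$explained_variance[2]))
}

res19 <- run_model(X, "model19")
res3 <- run_model(X[, markers], "model3")
message("validation outputs -> results/model19_*, results/model3_*")
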