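#!/usr/bin/env Rscript
# Standardize the patient features against the healthy-control
# reference, rank every coefficient by its ROC area (the "z-value"),
# prune correlated features, and report the top-15 list together with a
# PCA scatter of the reduced set.

library(eegresp)

ft <- readRDS("scratch/features_wavelet.rds")
ref <- fit_reference(ft$controls)
std <- standardize(ft$patients, ref)
saveRDS(list(std = std, ref = ref), "scratch/standardized.rds")

ranked <- auc_rank(std)
ranked <- prune_correlated(ranked, std, r_max = 0.9, n_keep = 100)
top15 <- take_top(ranked, 15)
pos <- fm_labels(std)

tab <- data.frame(
  channel = std$feature_meta$channel[top15],
  band = std$feature_meta$band[top15],
  abs_z = round(abs(ranked$auc[top15]), 4),
  p_value = sapply(top15, function(j) round(suppressWarnings(
    wilcox.test(std$values[pos, j], std$values[!pos, j])$p.value), 4)))
write.csv(tab, "results/top15_features.csv", row.names = FALSE)
message("top-15 ranked wavelet features (channel / band / |z| / p):")
print(tab)
message(sprintf("on effect channels (F7/F8/T4): %d of 15",
                sum(tab$channel %in% c("F7", "F8", "T4"))))

pca <- pca_scatter(fm_subset(std, cols = top15))
write.csv(data.frame(pca$scores, group = std$instance_meta$group,
                     condition = std$instance_meta$condition),
          "results/pca_scores.csv", row.names = FALSE)
message(sprintf("first two PCs explain %.1f%% of the reduced set",
                100 * sum(pca$variance_explained[1:2])))
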