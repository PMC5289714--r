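#!/usr/bin/env Rscript
# Wilcoxon rank-sum scalp topographies of the standardized delta/theta
# wavelet features: per channel a two-sided rank-sum test between
# responders and non-responders at the 5% level, pooled and stratified
# by sex, for each recording condition. The KS gate motivates the
# non-parametric choice.

library(eegresp)

std <- readRDS("scratch/standardized.rds")$std
ranked <- auc_rank(std)

# normality gate on the top-ranked standardized features
gate <- sapply(head(ranked$order, 15), function(j)
  ks_normality(std$values[, j]))
message(sprintf("KS gate: standard normality rejected for %d of 15 top features",
                sum(gate)))

dir.create("results", showWarnings = FALSE)
strata <- expand.grid(sex = c(NA, "F", "M"), condition = c("EC", "EO"),
                      stringsAsFactors = FALSE)
for (i in seq_len(nrow(strata))) {
  sx <- strata$sex[i]; cd <- strata$condition[i]
  mp <- wilcoxon_channel_map(std, ranked, top_n = 15, fallback_top_n = 100,
                             stratum_sex = if (is.na(sx)) NULL else sx,
                             stratum_condition = cd)
  if (is.null(mp)) next
  nm <- sprintf("map_%s_%s", ifelse(is.na(sx), "all", sx), cd)
  write.csv(mp, file.path("results", paste0(nm, ".csv")), row.names = FALSE)
  png(file.path("results", paste0(nm, ".png")), width = 480, height = 480)
  plot(mp)
  dev.off()
  message(sprintf("%s: %d of 19 channels significant (%s)", nm, sum(mp$H),
                  paste(mp$channel[mp$H == 1], collapse = ", ")))
}
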