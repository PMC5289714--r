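#!/usr/bin/env Rscript
# Preprocess every recording (0.1-70 Hz band-pass, 50 Hz notch, average
# re-reference, resampling to the 140 Hz dyadic analysis rate) and
# extract the wavelet feature family: db4 delta- and theta-block
# coefficients per channel, one instance per (subject, condition).

library(eegresp)

stopifnot(file.exists("scratch/cohort.rds"))
cohort <- readRDS("scratch/cohort.rds")$cohort

cfg <- preprocess_config(bandpass = c(0.1, 70), notch = 50,
                         reference = "average", resample_to = 140,
                         epoch_length = 60)

is_patient <- sapply(cohort$recordings, function(r) r$group %in% c("R", "NR"))
message("extracting wavelet features (patients)...")
fm_pat <- extract_features(cohort$recordings[is_patient],
                           method = "wavelet", cfg = cfg)
message("extracting wavelet features (controls)...")
fm_ctl <- extract_features(cohort$recordings[!is_patient],
                           method = "wavelet", cfg = cfg)
saveRDS(list(patients = fm_pat, controls = fm_ctl, cfg = cfg),
        "scratch/features_wavelet.rds")

message(sprintf("feature matrix: %d instances x %d features (%s)",
                nrow(fm_pat$values), ncol(fm_pat$values),
                paste(unique(fm_pat$feature_meta$band), collapse = "+")))
summary_tab <- aggregate(index ~ channel + band, fm_pat$feature_meta,
                         length)
names(summary_tab)[3] <- "n_coefficients"
write.csv(summary_tab, "results/feature_counts.csv", row.names = FALSE)
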