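cohort_small <- generate_cohort(reduced_spec(seed = 40, n_patients = 4,
                                             n_controls = 2, duration = 8))

test_that("wavelet extraction yields one tagged row per instance", {
  fm <- extract_features(cohort_small$recordings, method = "wavelet",
                         preprocess = FALSE, cfg = reduced_cfg(8))
  expect_equal(nrow(fm$values), 12)               # 6 subjects x EC/EO
  lens <- dwt_block_lengths(8 * 70, 3)
  expect_equal(ncol(fm$values), 2 * lens[3] * 19) # delta + theta per channel
  expect_setequal(unique(fm$feature_meta$band), c("delta", "theta"))
  expect_setequal(unique(fm$feature_meta$channel), montage_1020())
  expect_identical(fm$instance_meta$condition, rep(c("EC", "EO"), 6))
  expect_false(anyNA(fm$values))
})

test_that("the preprocessing chain is applied when requested", {
  fm_raw <- extract_features(cohort_small$recordings[1:2],
                             method = "wavelet", preprocess = FALSE,
                             cfg = reduced_cfg(8))
  fm_pp <- extract_features(cohort_small$recordings[1:2],
                            method = "wavelet", preprocess = TRUE,
                            cfg = reduced_cfg(8))
  expect_equal(dim(fm_pp$values), dim(fm_raw$values))
  expect_false(isTRUE(all.equal(fm_pp$values, fm_raw$values)))
})

test_that("other feature families produce consistent matrices", {
  recs <- cohort_small$recordings[1:4]
  fm_stft <- extract_features(recs, method = "stft", preprocess = FALSE,
                              cfg = reduced_cfg(8))
  expect_equal(nrow(fm_stft$values), 4)
  expect_equal(ncol(fm_stft$values), 19 * 2 * (floor((8 - 2) / 0.5) + 1))
  fm_psd <- extract_features(recs, method = "psd", preprocess = FALSE,
                             cfg = reduced_cfg(8))
  expect_equal(ncol(fm_psd$values), 19 * 4)       # delta..beta per channel
  fm_coh <- extract_features(recs[1:2], method = "coherence",
                             preprocess = FALSE, cfg = reduced_cfg(8))
  expect_equal(ncol(fm_coh$values), choose(19, 2) * 29)
  expect_true(all(fm_coh$values >= 0 & fm_coh$values <= 1))
})

test_that("EMD cohort features have a fixed length across instances", {
  recs <- cohort_small$recordings[1:3]
  fm <- extract_features(recs, method = "emd", preprocess = FALSE,
                         cfg = reduced_cfg(8))
  expect_equal(nrow(fm$values), 3)
  expect_equal(ncol(fm$values), 19 * 8 * 70)      # per-channel samples
})

test_that("diagnosis relabeling collapses patients to MDD", {
  fm <- extract_features(cohort_small$recordings, method = "psd",
                         preprocess = FALSE, cfg = reduced_cfg(8))
  dfm <- as_diagnosis_task(fm)
  expect_setequal(unique(dfm$instance_meta$group), c("MDD", "control"))
  expect_identical(fm_labels(dfm), dfm$instance_meta$group == "MDD")
})

test_that("cohorts round-trip through the CSV writer", {
  dir <- withr::local_tempdir()
  tiny <- generate_cohort(reduced_spec(seed = 41, n_patients = 2,
                                       n_controls = 1, duration = 2))
  write_cohort_csv(tiny, dir)
  back <- read_cohort_csv(dir)
  expect_equal(length(back$recordings), length(tiny$recordings))
  expect_equal(back$recordings[[1]]$data, tiny$recordings[[1]]$data,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$recordings[[3]]$condition,
                   tiny$recordings[[3]]$condition)
  expect_equal(back$metadata$pre_bdi, tiny$metadata$pre_bdi)
})
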