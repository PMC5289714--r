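test_that("responder and non-responder counts follow the configured fraction", {
  spec <- reduced_spec(seed = 42, duration = 2, n_controls = 4)
  ch <- generate_cohort(spec)
  md <- ch$metadata
  expect_equal(sum(md$group == "R"), 16)
  expect_equal(sum(md$group == "NR"), 18)
  expect_equal(sum(md$group == "control"), 4)
  # sexes balanced within each group
  expect_equal(unname(table(md$sex[md$group == "R"])), c(8L, 8L),
               ignore_attr = TRUE)
  expect_equal(unname(table(md$sex[md$group == "NR"])), c(9L, 9L),
               ignore_attr = TRUE)
  # one EC and one EO recording per subject
  conds <- table(sapply(ch$recordings, `[[`, "condition"))
  expect_equal(unname(conds[c("EC", "EO")]), c(38L, 38L),
               ignore_attr = TRUE)
})

test_that("a fixed seed reproduces the cohort bit-for-bit", {
  spec <- reduced_spec(seed = 7, n_patients = 4, duration = 2)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  spec2 <- reduced_spec(seed = 8, n_patients = 4, duration = 2)
  expect_false(identical(generate_cohort(spec), generate_cohort(spec2)))
})

test_that("the planted delta log-power contrast is recovered by Welch PSD", {
  # 100 subjects per group; the Welch measurement at an effect channel
  # must land within 15% of the planted group contrast in log power
  spec <- reduced_spec(seed = 11, n_patients = 200, duration = 20)
  spec$responder_fraction <- 0.5
  ch <- generate_cohort(spec)
  ec <- Filter(function(r) r$condition == "EC", ch$recordings)
  grp <- sapply(ec, `[[`, "group")
  f7 <- match("F7", montage_1020())
  cz <- match("Cz", montage_1020())
  lp <- function(r, chan) log(band_power(r$data[chan, ], r$fs, 0.5, 4))
  contrast <- mean(sapply(ec[grp == "R"], lp, chan = f7)) -
    mean(sapply(ec[grp == "NR"], lp, chan = f7))
  planted <- spec$effect_size * spec$subject_log_power_sd
  expect_lt(abs(contrast - planted), 0.15 * planted)
  # a non-effect channel shows no systematic contrast
  null_contrast <- mean(sapply(ec[grp == "R"], lp, chan = cz)) -
    mean(sapply(ec[grp == "NR"], lp, chan = cz))
  expect_lt(abs(null_contrast), 0.35)   # ~3 SE of the group-mean difference
})

test_that("eyes-closed recordings carry more alpha power than eyes-open", {
  spec <- reduced_spec(seed = 3, n_patients = 6, duration = 10)
  ch <- generate_cohort(spec)
  o1 <- match("O1", montage_1020())
  for (s in seq(1, 12, by = 2)) {
    ec <- ch$recordings[[s]]; eo <- ch$recordings[[s + 1]]
    expect_identical(c(ec$condition, eo$condition), c("EC", "EO"))
    expect_gt(band_power(ec$data[o1, ], ec$fs, 8.5, 17.5),
              band_power(eo$data[o1, ], eo$fs, 8.5, 17.5))
  }
})

test_that("label_response implements the 50%-improvement rule", {
  expect_equal(label_response(18.4, 9.1), "R")    # 50.5% improvement
  expect_equal(label_response(20, 10), "R")       # boundary: exactly 50%
  expect_equal(label_response(22.8, 22.1), "NR")  # 3.1% improvement
  expect_error(label_response(0, 5), "positive")
  # generated questionnaire scores always agree with the planted label
  md <- generate_cohort(reduced_spec(seed = 21, duration = 2))$metadata
  pat <- md[md$group != "control", ]
  expect_identical(label_response(pat$pre_bdi, pat$post_bdi), pat$group)
  expect_true(all(is.na(md$pre_bdi[md$group == "control"])))
})

test_that("sample_size truncates the precision formula", {
  expect_identical(sample_size(0.90, 0.10, 0.05), 34L)
  expect_identical(sample_size(0.5, 10, 0.05), 0L)
  expect_identical(sample_size(0.5, 0.5, 0.05), 3L)  # 3.8416 truncated
  expect_error(sample_size(1.2, 0.1))
  expect_error(sample_size(0.5, -1))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(responder_fraction = 1.4), "responder_fraction")
  expect_error(cohort_spec(fs = 128), "gamma")
  expect_error(cohort_spec(effect_channels = character(0), effect_size = 1),
               "effect_channels")
  expect_error(cohort_spec(effect_channels = c("F7", "XX")), "10-20")
})

test_that("configured artifacts appear in the signal", {
  # line noise sits at 50 Hz, outside the reduced 72 Hz band set: use the
  # full-rate generator here
  spec <- cohort_spec(n_patients = 2, n_controls = 0,
                      duration_per_condition = 10,
                      artifact_config = list(blink_rate = 12,
                                             line_amplitude = 3),
                      seed = 5)
  clean <- cohort_spec(n_patients = 2, n_controls = 0,
                       duration_per_condition = 10, seed = 5)
  rec <- generate_cohort(spec)$recordings[[1]]
  rec0 <- generate_cohort(clean)$recordings[[1]]
  fp1 <- match("Fp1", montage_1020())
  p50 <- band_power(rec$data[fp1, ], rec$fs, 49, 51)
  p50_clean <- band_power(rec0$data[fp1, ], rec0$fs, 49, 51)
  expect_gt(p50, p50_clean + 0.5 * 3^2)  # planted 50 Hz power ~ amplitude^2
  expect_gt(max(abs(rec$data[fp1, ])), max(abs(rec0$data[fp1, ])))
})
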