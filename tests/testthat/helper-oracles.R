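# Independent oracles and small fixtures shared across the suite.

# Brute-force Mann-Whitney AUC - 0.5 by exhaustive pair counting,
# half credit for tied values.
oracle_auc <- function(x, pos) {
  p <- which(pos); n <- which(!pos)
  gt <- eq <- 0
  for (i in p) {
    gt <- gt + sum(x[i] > x[n])
    eq <- eq + sum(x[i] == x[n])
  }
  (gt + 0.5 * eq) / (length(p) * length(n)) - 0.5
}

# Exact two-sided rank-sum p-value by enumerating every group assignment
# (feasible for n1, n2 <= 8); doubling convention as in wilcox.test.
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(x), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# The printed worked-example data: ten instances, features "i" and "j",
# binary labels (+/-).
roc_example <- function() {
  data.frame(
    i = c(-0.2, -1.4, 0.8, -0.8, 0.1, 0.5, 1.6, -2.1, -0.3, 3.4),
    j = c(0.5, -1.4, -0.9, 0.2, -2.5, 1.4, -0.3, -1.2, 2.2, -1.7),
    label = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
              FALSE)
  )
}

# A reduced synthetic cohort for Monte-Carlo work: the planted contrast
# parameters stay at package defaults; recording length, sampling rate
# and band set are scaled down (no gamma band, so the dyadic analysis
# rate 70 Hz with 3 decomposition levels reaches the same delta/theta
# edges as 140 Hz with 4 levels).
reduced_spec <- function(seed, n_patients = 34, n_controls = 0,
                         effect_size = 1.5, duration = 10, ...) {
  cohort_spec(
    n_patients = n_patients, n_controls = n_controls,
    responder_fraction = 16 / 34, fs = 72,
    duration_per_condition = duration,
    band_amplitudes = list(delta = 20, theta = 10,
                           alpha = c(EC = 15, EO = 7.5), beta = 5),
    effect_size = effect_size, seed = seed, ...)
}

reduced_cfg <- function(duration = 10)
  preprocess_config(bandpass = c(0.1, 30), notch = NULL, resample_to = 70,
                    epoch_length = duration)

# wavelet feature matrix of a reduced cohort (synthetic recordings are
# generated clean and band-limited, so the filtering stage is bypassed)
reduced_features <- function(cohort, duration = 10) {
  extract_features(cohort$recordings, method = "wavelet",
                   preprocess = FALSE, cfg = reduced_cfg(duration))
}

sine <- function(f, fs, dur, amp = 1, phase = 0)
  amp * sin(2 * pi * f * (0:(round(fs * dur) - 1)) / fs + phase)

# minimal multichannel recording around a given matrix
rec_of <- function(data, fs = 256, labels = NULL, ...) {
  if (is.null(labels))
    labels <- montage_1020()[seq_len(nrow(data))]
  eeg_recording(data, fs, channel_labels = labels, ...)
}

# feature matrix with one column per montage channel, built directly
# from per-instance channel scalars (for topography statistics)
channel_fm <- function(values, groups, sexes = NULL, conditions = NULL) {
  n <- nrow(values)
  feature_matrix(
    values,
    data.frame(feature = paste0("ch_", montage_1020()),
               channel = montage_1020(), band = "delta", method = "wavelet",
               index = seq_len(ncol(values)), stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               condition = conditions %||% rep("EC", n),
               group = groups,
               sex = sexes %||% rep(c("F", "M"), length.out = n),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
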