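#' Simulate a 3-stimulus visual oddball ERP recording
#'
#' Generates one event-related recording: ongoing background EEG plus a
#' stereotyped positive deflection (the P300) time-locked to each Target
#' stimulus, strongest over centro-parietal sites and falling off with
#' scalp distance from Pz. Stimulus order is random with the requested
#' counts; default counts (314 Standard / 45 Distractor / 41 Target) match
#' the oddball design the package emulates.
#'
#' @param fs sampling rate (Hz).
#' @param n_target,n_standard,n_distractor stimulus counts.
#' @param soa stimulus-onset asynchrony in seconds.
#' @param p300_amplitude planted peak amplitude in microvolts at Pz.
#' @param p300_latency planted peak latency in seconds after Target onset.
#' @param noise_rms RMS of the ongoing background activity (microvolts);
#'   0 gives a noise-free recording.
#' @param subject_id,group,sex metadata passed to [eeg_recording()].
#' @param seed optional seed; `NULL` uses the current RNG state (so the
#'   cohort generator stays reproducible as a whole).
#' @return An [eeg_recording()] with `condition = "ERP"` and an event log.
#' @export
simulate_erp_recording <- function(fs = 256, n_target = 41, n_standard = 314,
                                   n_distractor = 45, soa = 1.5,
                                   p300_amplitude = 5, p300_latency = 0.4,
                                   noise_rms = 4, subject_id = "S01",
                                   group = "R", sex = "F", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stimuli <- sample(rep(c("Target", "Standard", "Distractor"),
                        c(n_target, n_standard, n_distractor)))
  onsets <- round(seq_along(stimuli) * soa * fs)   # 1 SOA of lead-in
  n <- max(onsets) + round(1.2 * fs)
  labels <- montage_1020()
  n_ch <- length(labels)

  sig <- if (noise_rms > 0)
    noise_rms * .pink_noise(n, fs, n_ch) +
      noise_rms * .bandlimited_noise(n, fs, 8.5, 17.5, n_ch)
  else matrix(0, n, n_ch)

  # smooth unimodal P300 waveform peaking exactly at p300_latency
  tw <- seq(0, 0.8, by = 1 / fs)
  wave <- exp(-((tw - p300_latency) / 0.08)^2)
  coords <- montage_coordinates()
  pz <- coords[coords$channel == "Pz", ]
  w_ch <- exp(-sqrt((coords$x - pz$x)^2 + (coords$y - pz$y)^2) / 0.6)
  for (o in onsets[stimuli == "Target"]) {
    idx <- o:(o + length(wave) - 1)
    keep <- idx <= n
    sig[idx[keep], ] <- sig[idx[keep], ] +
      p300_amplitude * outer(wave[keep], w_ch)
  }

  eeg_recording(t(sig), fs, labels, subject_id = subject_id, group = group,
                sex = sex, condition = "ERP",
                events = data.frame(sample = onsets, stimulus = stimuli,
                                    stringsAsFactors = FALSE))
}

#' Extract P300 amplitude and latency per channel
#'
#' Epochs the recording around each Target onset, subtracts the
#' pre-stimulus baseline mean, averages across trials, and reads the P300
#' as the maximum of the average waveform inside the search window
#' (positive-going peak by convention; 300-700 ms by default).
#'
#' @param erp an ERP [eeg_recording()] with an event log.
#' @param stimulus stimulus class to average (default `"Target"`).
#' @param window search window in seconds after stimulus onset.
#' @param baseline pre-stimulus baseline duration in seconds.
#' @return Data frame with one row per channel: `channel`,
#'   `p300_amplitude` (microvolts), `p300_latency` (ms),
#'   `n_trials_averaged`.
#' @export
p300_extract <- function(erp, stimulus = "Target", window = c(0.3, 0.7),
                         baseline = 0.1) {
  stopifnot(inherits(erp, "eeg_recording"))
  if (is.null(erp$events)) stop("recording carries no event log")
  onsets <- erp$events$sample[erp$events$stimulus == stimulus]
  fs <- erp$fs
  n <- ncol(erp$data)
  post <- round(window[2] * fs)
  pre <- round(baseline * fs)
  onsets <- onsets[onsets - pre >= 1 & onsets + post <= n]
  if (length(onsets) == 0)
    stop("no '", stimulus, "' events with a complete epoch window")

  n_ch <- nrow(erp$data)
  avg <- matrix(0, n_ch, post + 1)
  for (o in onsets) {
    epoch <- erp$data[, (o - pre):(o + post), drop = FALSE]
    bl <- rowMeans(epoch[, seq_len(pre), drop = FALSE])
    avg <- avg + (epoch[, (pre + 1):(pre + post + 1), drop = FALSE] - bl)
  }
  avg <- avg / length(onsets)

  tgrid <- (0:post) / fs
  inwin <- which(tgrid >= window[1] & tgrid <= window[2])
  peak <- apply(avg[, inwin, drop = FALSE], 1, which.max)
  data.frame(
    channel = erp$channel_labels,
    p300_amplitude = avg[cbind(seq_len(n_ch), inwin[peak])],
    p300_latency = tgrid[inwin[peak]] * 1000,
    n_trials_averaged = length(onsets),
    stringsAsFactors = FALSE
  )
}

#' Grand-average ERP across recordings
#'
#' Averages the per-subject Target-locked average waveforms of several
#' recordings (equal weight per subject).
#'
#' @param recs list of ERP recordings.
#' @param ... passed to [p300_extract()].
#' @return Data frame as from [p300_extract()], averaged across subjects
#'   (latency re-derived from the averaged amplitudes is not attempted;
#'   amplitudes and latencies are averaged directly).
#' @export
p300_grand_average <- function(recs, ...) {
  per <- lapply(recs, p300_extract, ...)
  out <- per[[1]]
  out$p300_amplitude <- rowMeans(sapply(per, `[[`, "p300_amplitude"))
  out$p300_latency <- rowMeans(sapply(per, `[[`, "p300_latency"))
  out$n_trials_averaged <- sum(sapply(per, function(p) p$n_trials_averaged[1]))
  out
}
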