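#' Preprocessing configuration
#'
#' @param bandpass band-pass edges in Hz (`c(low, high)`).
#' @param notch notch frequency in Hz (`NULL` disables).
#' @param notch_q quality factor of the notch biquad.
#' @param reference `"average"` re-references to the common average;
#'   `"as-recorded"` leaves the (linked-ear) recording reference in place.
#' @param resample_to target analysis rate in Hz (`NULL` keeps the native
#'   rate). The default 140 Hz makes the 5-level dyadic wavelet bands land
#'   on the edges in [eeg_bands()].
#' @param epoch_length analysis epoch length in seconds.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass = c(0.1, 70), notch = 50,
                              notch_q = 30,
                              reference = c("average", "as-recorded"),
                              resample_to = 140, epoch_length = 120) {
  reference <- match.arg(reference)
  stopifnot(length(bandpass) == 2, bandpass[1] > 0,
            bandpass[1] < bandpass[2])
  if (!is.null(notch) && (notch <= bandpass[1] || notch >= bandpass[2]))
    stop("`notch` must lie inside the band-pass")
  structure(list(bandpass = bandpass, notch = notch, notch_q = notch_q,
                 reference = reference, resample_to = resample_to,
                 epoch_length = epoch_length),
            class = "preprocess_config")
}

# RBJ-cookbook second-order IIR notch at f0 with quality factor Q
.notch_coefs <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase (forward-backward) IIR filtering: a 4th-order Butterworth
#' band-pass realized as a 2nd-order high-pass cascaded with a 2nd-order
#' low-pass (numerically safer than a direct band-pass when the low edge
#' sits far below Nyquist), followed by a 2nd-order 50 Hz notch. Defaults
#' reproduce the acquisition chain the pipeline assumes: 0.1-70 Hz plus a
#' 50 Hz power-line notch.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [preprocess_config()].
#' @return The filtered recording (shape preserved).
#' @export
filter_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (cfg$bandpass[2] >= nyq * 0.99)
    stop("band-pass high edge too close to Nyquist (", nyq, " Hz)")
  hp <- signal::butter(2, cfg$bandpass[1] / nyq, type = "high")
  lp <- signal::butter(2, cfg$bandpass[2] / nyq, type = "low")
  x <- t(rec$data)
  # remove the DC level first: the 0.1 Hz high-pass has a time constant
  # of seconds, so forward-backward filtering alone leaves edge leakage
  x <- sweep(x, 2, colMeans(x), "-")
  for (j in seq_len(ncol(x))) {
    y <- signal::filtfilt(hp, x[, j])
    y <- signal::filtfilt(lp, y)
    if (!is.null(cfg$notch)) {
      nc <- .notch_coefs(cfg$notch, rec$fs, cfg$notch_q)
      y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
    }
    x[, j] <- y
  }
  rec$data <- t(x)
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample mean across channels from every channel, so
#' each column of the data sums to zero. Used in place of a model-based
#' infinity reference, which needs a head model; common-average and
#' infinity referencing are treated as interchangeable here.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop("average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec
}

#' Extract a contiguous epoch
#'
#' Cuts `length` seconds starting `offset` seconds into the recording,
#' using 0-based half-open sample indexing: samples
#' `[offset * fs, (offset + length) * fs)`.
#'
#' @param rec an [eeg_recording()].
#' @param length epoch length in seconds (default 120: the two-minute
#'   analysis window the pipeline reports on).
#' @param offset start time in seconds (default 0).
#' @return The epoch as an [eeg_recording()], metadata preserved.
#' @export
extract_epoch <- function(rec, length = 120, offset = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  start <- round(offset * rec$fs)          # 0-based
  stop_ <- start + round(length * rec$fs)  # half-open
  if (start < 0 || stop_ > ncol(rec$data))
    stop("epoch [", offset, ", ", offset + length,
         ") s out of range for a ", recording_duration(rec), " s recording")
  rec$data <- rec$data[, (start + 1):stop_, drop = FALSE]
  if (!is.null(rec$events)) {
    keep <- rec$events$sample > start & rec$events$sample <= stop_
    rec$events <- rec$events[keep, , drop = FALSE]
    rec$events$sample <- rec$events$sample - start
  }
  rec
}

#' Resample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated (or the signal
#' rejected, for upsampling) and inverse-transformed on the target grid,
#' preserving duration to within one sample. Exact for signals already
#' band-limited below the new Nyquist rate, which holds for the 0.1-70 Hz
#' filtered recordings resampled to 140 Hz ahead of the wavelet stage.
#'
#' @param rec an [eeg_recording()].
#' @param fs_target target rate in Hz; must not exceed the native rate.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, fs_target = 140) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_target > rec$fs) stop("upsampling is not supported")
  if (fs_target == rec$fs) return(rec)
  n <- ncol(rec$data)
  m <- round(n * fs_target / rec$fs)
  spec <- mvfft(t(rec$data))
  p <- floor((m - 1) / 2)                  # strictly positive bins kept
  out <- matrix(0 + 0i, m, nrow(rec$data))
  out[1, ] <- spec[1, ]
  if (p > 0) {
    out[2:(p + 1), ] <- spec[2:(p + 1), ]
    out[(m - p + 1):m, ] <- spec[(n - p + 1):n, ]
  }
  if (m %% 2 == 0)                         # fold both old bins into new Nyquist
    out[m / 2 + 1, ] <- Re(spec[m / 2 + 1, ] + spec[n - m / 2 + 1, ]) / 2
  rec$data <- t(Re(mvfft(out, inverse = TRUE)) / n)
  if (!is.null(rec$events))
    rec$events$sample <- pmax(1, round(rec$events$sample * fs_target / rec$fs))
  rec$fs <- fs_target
  rec
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Plumbing utility (off by default in the pipeline): splits a recording
#' into consecutive windows and drops windows whose peak absolute
#' amplitude exceeds a threshold, concatenating the survivors.
#'
#' @param rec an [eeg_recording()].
#' @param threshold amplitude threshold in microvolts.
#' @param window window length in seconds.
#' @return The recording with offending windows removed.
#' @export
reject_amplitude <- function(rec, threshold = 100, window = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- round(window * rec$fs)
  n_win <- floor(ncol(rec$data) / w)
  keep <- logical(0)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1) * w + 1):(k * w)
    keep <- c(keep, rep(max(abs(rec$data[, idx])) <= threshold, w))
  }
  keep <- c(keep, rep(TRUE, ncol(rec$data) - length(keep)))
  rec$data <- rec$data[, keep, drop = FALSE]
  rec
}
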