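#' Welch averaged-periodogram power spectral density
#'
#' Hamming-windowed, 50%-overlapping segment-averaged periodogram,
#' scaled as a one-sided density so that the integral over frequency
#' equals the signal variance (Parseval).
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @param demean subtract the signal mean before estimation.
#' @return List with `freq` (Hz) and `psd` (power per Hz), plus
#'   `n_segments`.
#' @export
welch_psd <- function(signal, fs, window_s = 2, overlap = 0.5,
                      demean = TRUE) {
  w <- welch_cross(signal, signal, fs, window_s, overlap, demean)
  list(freq = w$freq, psd = Re(w$sxy), n_segments = w$n_segments)
}

#' Welch cross-spectral density
#'
#' Segment-averaged cross-spectrum of two equal-length signals with the
#' same windowing and scaling as [welch_psd()] (with `x = y` it reduces
#' to the auto-PSD). Used as the building block for magnitude-squared
#' coherence.
#'
#' @inheritParams welch_psd
#' @param x,y numeric vectors of equal length.
#' @return List with `freq`, complex `sxy`, and `n_segments`.
#' @export
welch_cross <- function(x, y, fs, window_s = 2, overlap = 0.5,
                        demean = TRUE) {
  stopifnot(length(x) == length(y))
  nw <- round(window_s * fs)
  if (length(x) < nw) stop("signal shorter than one analysis window")
  hop <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = hop)
  win <- .hamming(nw)
  u <- sum(win^2)                        # window power normalization
  half <- floor(nw / 2) + 1
  acc <- complex(real = numeric(half), imaginary = numeric(half))
  if (demean) { x <- x - mean(x); y <- y - mean(y) }
  for (s in starts) {
    seg_x <- fft(x[s:(s + nw - 1)] * win)[1:half]
    seg_y <- fft(y[s:(s + nw - 1)] * win)[1:half]
    acc <- acc + seg_x * Conj(seg_y)
  }
  sxy <- acc / (length(starts) * u * fs)
  # one-sided scaling: double all bins except DC (and Nyquist when present)
  scale2 <- rep(2, half); scale2[1] <- 1
  if (nw %% 2 == 0) scale2[half] <- 1
  list(freq = (0:(half - 1)) * fs / nw, sxy = sxy * scale2,
       n_segments = length(starts))
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Band power from a Welch PSD
#'
#' Integrates the one-sided Welch density over `[low, high)` by the
#' rectangle rule on the FFT bin grid.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges in Hz.
#' @param ... passed to [welch_psd()].
#' @return Band power (same units as signal variance).
#' @export
band_power <- function(signal, fs, low, high, ...) {
  w <- welch_psd(signal, fs, ...)
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[w$freq >= low & w$freq < high]) * df
}

#' Short-time Fourier transform spectrogram
#'
#' Hamming-windowed, zero-padded power spectrogram (density scaling, one
#' sided). The frame count is `floor((n_samples - window) / hop) + 1`.
#'
#' @inheritParams stft_features
#' @return List with `freq` (Hz), `time` (frame centers, s), and `power`
#'   (freq x frames matrix).
#' @export
stft_spectrogram <- function(signal, fs, window_s = 2, hop_s = 0.5,
                             nfft = 4096) {
  nw <- round(window_s * fs)
  hop <- round(hop_s * fs)
  if (length(signal) < nw) stop("signal shorter than one STFT window")
  if (nfft < nw) stop("`nfft` must be at least the window length in samples")
  starts <- seq(1, length(signal) - nw + 1, by = hop)
  win <- .hamming(nw)
  u <- sum(win^2)
  half <- floor(nfft / 2) + 1
  P <- matrix(0, half, length(starts))
  for (k in seq_along(starts)) {
    seg <- signal[starts[k]:(starts[k] + nw - 1)] * win
    P[, k] <- (Mod(fft(c(seg, rep(0, nfft - nw))))^2 / (u * fs))[1:half]
  }
  P[2:(half - 1), ] <- 2 * P[2:(half - 1), ]
  list(freq = (0:(half - 1)) * fs / nfft,
       time = (starts - 1 + nw / 2) / fs, power = P)
}

#' Short-time Fourier transform features
#'
#' Hamming-windowed spectrogram (2 s window, 0.5 s hop, 4096-point FFT by
#' default) reduced to log band power per frame in the requested bands.
#' The frame count is `floor((n_samples - window) / hop) + 1`.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds.
#' @param hop_s hop between consecutive frames in seconds.
#' @param nfft FFT length (zero-padded; must be at least the window
#'   length in samples).
#' @param bands band names (rows of [eeg_bands()]) retained as features.
#' @param channel channel label recorded in the metadata.
#' @param floor_db log-power floor in decibels, applied before taking
#'   logs so silent frames stay finite.
#' @return List with `values` (log10 band power per (band, frame),
#'   flattened frame-fastest) and `meta` (data frame: `channel`, `band`,
#'   `frame`, `index`); also attribute-free helper fields `n_frames`.
#' @export
stft_features <- function(signal, fs, window_s = 2, hop_s = 0.5,
                          nfft = 4096, bands = c("delta", "theta"),
                          channel = NA_character_, floor_db = -120) {
  nw <- round(window_s * fs)
  hop <- round(hop_s * fs)
  if (length(signal) < nw) stop("signal shorter than one STFT window")
  if (nfft < nw) stop("`nfft` must be at least the window length in samples")
  starts <- seq(1, length(signal) - nw + 1, by = hop)
  win <- .hamming(nw)
  u <- sum(win^2)
  freqs <- (0:(nfft - 1)) * fs / nfft
  band_tbl <- eeg_bands()
  band_tbl <- band_tbl[band_tbl$band %in% bands, , drop = FALSE]

  frames <- matrix(0, nrow(band_tbl), length(starts))
  for (k in seq_along(starts)) {
    seg <- signal[starts[k]:(starts[k] + nw - 1)] * win
    spec <- Mod(fft(c(seg, rep(0, nfft - nw))))^2 / (u * fs)
    for (b in seq_len(nrow(band_tbl))) {
      sel <- freqs >= band_tbl$low[b] & freqs < band_tbl$high[b]
      frames[b, k] <- 2 * sum(spec[sel]) * fs / nfft
    }
  }
  vals <- log10(pmax(frames, 10^(floor_db / 10)))
  meta <- data.frame(
    channel = channel,
    band = rep(band_tbl$band, each = length(starts)),
    frame = rep(seq_along(starts), nrow(band_tbl)),
    stringsAsFactors = FALSE)
  meta$index <- seq_len(nrow(meta))
  list(values = as.vector(t(vals)), meta = meta,
       n_frames = length(starts))
}

#' Magnitude-squared coherence between two signals
#'
#' `C_xy(f) = |S_xy(f)|^2 / (S_x(f) S_y(f))` estimated from Welch
#' auto- and cross-spectra with 2 s windows, evaluated on a 1 Hz grid
#' over 2-30 Hz by default. Bounded in `[0, 1]`, symmetric in the pair,
#' and invariant to amplitude scaling of either input. A single
#' averaging segment would make the estimate identically 1, so at least
#' two segments are required.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate (Hz).
#' @param window_s Welch segment length in seconds.
#' @param freq_range analysis range in Hz.
#' @param freq_step grid resolution in Hz.
#' @param overlap fractional segment overlap.
#' @return Object of class `coherence_spectrum`: list with `freq`,
#'   `coherence`, `s_x`, `s_y`, `s_xy`, `n_segments`.
#' @export
coherence <- function(x, y, fs, window_s = 2, freq_range = c(2, 30),
                      freq_step = 1, overlap = 0.5) {
  w <- welch_cross(x, y, fs, window_s, overlap)
  if (w$n_segments < 2)
    stop("coherence needs >= 2 averaging segments ",
         "(a single segment is identically 1)")
  sx <- Re(welch_cross(x, x, fs, window_s, overlap)$sxy)
  sy <- Re(welch_cross(y, y, fs, window_s, overlap)$sxy)
  grid <- seq(freq_range[1], freq_range[2], by = freq_step)
  idx <- vapply(grid, function(f) which.min(abs(w$freq - f)), integer(1))
  cxy <- Mod(w$sxy[idx])^2 / (sx[idx] * sy[idx])
  cxy[!is.finite(cxy)] <- 0
  structure(list(freq = grid, coherence = pmin(pmax(cxy, 0), 1),
                 s_x = sx[idx], s_y = sy[idx], s_xy = w$sxy[idx],
                 n_segments = w$n_segments),
            class = "coherence_spectrum")
}

#' All-pairs channel coherence of a recording
#'
#' Computes [coherence()] for every unordered channel pair (171 pairs for
#' the 19-channel montage) and returns the flattened coherence values as
#' a feature vector.
#'
#' @param rec an [eeg_recording()].
#' @param ... passed to [coherence()].
#' @return List with `values` and `meta` (data frame: `channel` =
#'   "ch1-ch2" pair label, `band` = frequency in Hz as character,
#'   `index`).
#' @export
coherence_features <- function(rec, ...) {
  labs <- rec$channel_labels
  pairs <- utils::combn(length(labs), 2)
  values <- numeric(0)
  chan <- freqv <- character(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    co <- coherence(rec$data[i, ], rec$data[j, ], rec$fs, ...)
    values <- c(values, co$coherence)
    chan <- c(chan, rep(paste0(labs[i], "-", labs[j]), length(co$freq)))
    freqv <- c(freqv, as.character(co$freq))
  }
  meta <- data.frame(channel = chan, band = freqv,
                     index = seq_along(values), stringsAsFactors = FALSE)
  list(values = values, meta = meta)
}
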