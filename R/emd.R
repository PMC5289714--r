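## Empirical mode decomposition by envelope sifting.

# indices of strict local maxima / minima
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus count once
  idx <- which(s[-1] != 0 & s[-length(s)] != 0 &
                 s[-1] != s[-length(s)]) + 1
  list(max = idx[x[idx] > x[idx - 1]], min = idx[x[idx] < x[idx - 1]])
}

.zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# cubic-spline envelope through the extrema; the outermost extrema are
# mirrored across both signal ends, the standard guard against spline
# end swings
.envelope <- function(x, idx) {
  n <- length(x)
  k <- length(idx)
  p <- idx
  v <- x[idx]
  nm <- min(2, k)
  pl <- 2 - rev(p[seq_len(nm)])
  vl <- rev(v[seq_len(nm)])
  pr <- 2 * n - rev(p[(k - nm + 1):k])
  vr <- rev(v[(k - nm + 1):k])
  allp <- c(pl, p, pr)
  allv <- c(vl, v, vr)
  keep <- !duplicated(allp)
  splinefun(allp[keep], allv[keep], method = "fmm")(seq_len(n))
}

#' Empirical mode decomposition
#'
#' Iterative sifting: local maxima and minima are detected, upper and
#' lower envelopes constructed by cubic-spline interpolation, and the
#' envelope mean subtracted until the candidate satisfies the two IMF
#' conditions (extrema and zero-crossing counts differing by at most one;
#' near-zero envelope mean) and the normalized squared-difference
#' stopping criterion falls below `sd_threshold`. Each accepted intrinsic
#' mode function (IMF) is subtracted and sifting restarts on the
#' remainder until the residue is monotone (or nearly oscillation-free)
#' or `max_imfs` is reached. By construction the IMFs plus the residue
#' sum back to the input.
#'
#' @param signal numeric vector with at least 4 extrema.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sd_threshold normalized squared-difference stopping threshold
#'   for the inner sifting loop (default 0.2).
#' @param resolution_db residual-energy stop for the outer loop:
#'   decomposition ends once the remainder carries this many decibels
#'   less energy than the input (default 40 dB), which prevents
#'   negligible spurious modes from being split off.
#' @param max_sift safety cap on sifting iterations per IMF.
#' @return Object of class `imf_set`: list with `imfs` (list of
#'   vectors), `residue`, `sift_counts`.
#' @export
emd_sift <- function(signal, max_imfs = 10, sd_threshold = 0.2,
                     resolution_db = 40, max_sift = 50) {
  x <- signal
  e0 <- sum(signal^2)
  imfs <- list()
  counts <- integer(0)
  repeat {
    ex <- .local_extrema(x)
    if (length(ex$max) < 2 || length(ex$min) < 2 ||
        length(imfs) >= max_imfs ||
        sum(x^2) < e0 * 10^(-resolution_db / 10)) break
    h <- x
    it <- 0
    repeat {
      it <- it + 1
      ex_h <- .local_extrema(h)
      if (length(ex_h$max) < 2 || length(ex_h$min) < 2) break
      m <- (.envelope(h, ex_h$max) + .envelope(h, ex_h$min)) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      imf_ok <- {
        ex_n <- .local_extrema(h_new)
        n_ext <- length(ex_n$max) + length(ex_n$min)
        abs(n_ext - .zero_crossings(h_new)) <= 1 &&
          mean(abs(h_new)) > 0 &&
          abs(mean(h_new)) / sqrt(mean(h_new^2)) < 0.05
      }
      h <- h_new
      if ((sd_crit < sd_threshold && imf_ok) || it >= max_sift) break
    }
    imfs[[length(imfs) + 1]] <- h
    counts <- c(counts, it)
    x <- x - h
  }
  structure(list(imfs = imfs, residue = x, sift_counts = counts),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs (sift counts: %s), residue RMS %.3g\n",
              length(x$imfs), paste(x$sift_counts, collapse = ", "),
              sqrt(mean(x$residue^2))))
  invisible(x)
}

#' Dominant frequency of a signal
#'
#' Frequency of the largest Welch PSD peak; used to decide which IMFs
#' fall in the delta/theta range.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param ... passed to [welch_psd()].
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(signal, fs, ...) {
  n <- length(signal)
  win_s <- min(2, n / fs)
  w <- welch_psd(signal, fs, window_s = win_s, ...)
  w$freq[which.max(w$psd)]
}

#' Band-selected EMD features
#'
#' Selects the IMFs whose dominant (Welch) frequency falls inside the
#' requested bands and returns their samples as the feature vector,
#' tagged with channel and IMF index.
#'
#' @param imfset an [emd_sift()] result.
#' @param fs sampling rate (Hz).
#' @param bands band names from [eeg_bands()].
#' @param channel channel label recorded in the metadata.
#' @return List with `values`, `meta` (data frame: `channel`, `band`,
#'   `imf`, `index`) and `selected` (IMF indices retained). Selecting no
#'   IMF yields an empty vector with a warning.
#' @export
emd_features <- function(imfset, fs, bands = c("delta", "theta"),
                         channel = NA_character_) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) < 1) stop("IMF set is empty")
  band_tbl <- eeg_bands()
  band_tbl <- band_tbl[band_tbl$band %in% bands, , drop = FALSE]
  values <- numeric(0)
  meta <- data.frame(channel = character(0), band = character(0),
                     imf = integer(0), stringsAsFactors = FALSE)
  selected <- integer(0)
  for (k in seq_along(imfset$imfs)) {
    f0 <- dominant_frequency(imfset$imfs[[k]], fs)
    hit <- which(f0 >= band_tbl$low & f0 < band_tbl$high)
    if (length(hit) == 1) {
      selected <- c(selected, k)
      v <- imfset$imfs[[k]]
      values <- c(values, v)
      meta <- rbind(meta, data.frame(
        channel = channel, band = band_tbl$band[hit],
        imf = k, stringsAsFactors = FALSE))
    }
  }
  if (length(selected) == 0)
    warning("no IMF with a dominant frequency in bands: ",
            paste(bands, collapse = ", "))
  if (nrow(meta) > 0) {
    meta <- meta[rep(seq_len(nrow(meta)),
                     times = lengths(imfset$imfs)[selected]), ]
    meta$index <- seq_len(nrow(meta))
    rownames(meta) <- NULL
  } else meta$index <- integer(0)
  list(values = values, meta = meta, selected = selected)
}
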