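#' Extract a cohort-level feature matrix
#'
#' Runs the preprocessing chain (band-pass + notch filter, average
#' re-reference, epoch extraction, and — for the wavelet family —
#' resampling to the dyadic analysis rate) on every recording and
#' assembles one feature row per (subject, condition) instance:
#'
#' * `wavelet`: delta- and theta-block db4 coefficients per channel,
#'   the primary feature family;
#' * `stft`: log band power per spectrogram frame (delta + theta bins);
#' * `emd`: samples of the per-channel delta/theta intrinsic-mode
#'   reconstruction (IMFs whose dominant frequency falls in the target
#'   bands, summed and resampled to the analysis rate — a fixed-length
#'   resolution of the variable IMF count across recordings);
#' * `psd`: Welch band power per channel and band (0.5-30 Hz bands);
#' * `coherence`: magnitude-squared coherence per channel pair on the
#'   2-30 Hz grid;
#' * `p300`: P300 amplitude and latency per channel (ERP recordings).
#'
#' @param recordings list of [eeg_recording()]s.
#' @param method feature family, see above.
#' @param bands band names retained (wavelet/stft/emd).
#' @param conditions recording conditions to keep as instances.
#' @param cfg a [preprocess_config()]; its `epoch_length` and
#'   `resample_to` drive the epoching/resampling. Epochs longer than a
#'   recording are truncated to the full recording.
#' @param epoch_offset epoch start in seconds.
#' @param preprocess apply filtering/re-referencing (disable for signals
#'   that are already clean, e.g. artifact-free synthetic data where
#'   speed matters).
#' @return A [feature_matrix()].
#' @export
extract_features <- function(recordings,
                             method = c("wavelet", "stft", "emd", "psd",
                                        "coherence", "p300"),
                             bands = c("delta", "theta"),
                             conditions = c("EC", "EO"),
                             cfg = preprocess_config(),
                             epoch_offset = 0,
                             preprocess = TRUE) {
  method <- match.arg(method)
  if (method == "p300") conditions <- "ERP"
  recs <- Filter(function(r) r$condition %in% conditions, recordings)
  if (length(recs) == 0) stop("no recordings in the requested conditions")

  rows <- vector("list", length(recs))
  meta <- NULL
  inst <- data.frame(subject_id = character(0), condition = character(0),
                     group = character(0), sex = character(0),
                     stringsAsFactors = FALSE)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (preprocess) {
      rec <- filter_recording(rec, cfg)
      if (cfg$reference == "average") rec <- rereference_average(rec)
    }
    if (rec$condition != "ERP") {
      len <- min(cfg$epoch_length, recording_duration(rec) - epoch_offset)
      rec <- extract_epoch(rec, len, epoch_offset)
    }
    ext <- .extract_one(rec, method, bands, cfg)
    rows[[i]] <- ext$values
    if (is.null(meta)) meta <- ext$meta
    inst <- rbind(inst, data.frame(
      subject_id = rec$subject_id, condition = rec$condition,
      group = rec$group, sex = rec$sex, stringsAsFactors = FALSE))
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("inconsistent feature-vector lengths across instances")
  meta$method <- method
  meta$feature <- sprintf("%s_%s_%s_%d", method, meta$channel,
                          if (!is.null(meta$band)) meta$band else "x",
                          seq_len(nrow(meta)))
  feature_matrix(do.call(rbind, rows), meta, inst)
}

.extract_one <- function(rec, method, bands, cfg) {
  switch(method,
    wavelet = {
      if (!is.null(cfg$resample_to) && cfg$resample_to != rec$fs)
        rec <- resample_recording(rec, cfg$resample_to)
      # depth such that the final approximation tops out at the dyadic
      # delta edge (fs / 2^(levels + 1) = 4.375 Hz): 4 at 140 Hz, 3 at 70
      levels <- max(1, round(log2(rec$fs / 8.75)))
      dec <- dwt_decompose(t(rec$data), levels = levels, fs = rec$fs)
      vals <- numeric(0)
      meta <- NULL
      for (b in bands) {
        for (blk in dec$band_map$block[dec$band_map$band == b]) {
          M <- dec$coeff_blocks[[blk]]          # coeffs x channels
          vals <- c(vals, as.vector(M))
          meta <- rbind(meta, data.frame(
            channel = rep(rec$channel_labels, each = nrow(M)),
            band = b, block = blk,
            index = rep(seq_len(nrow(M)), times = ncol(M)),
            stringsAsFactors = FALSE))
        }
      }
      list(values = vals, meta = meta)
    },
    stft = {
      vals <- numeric(0); meta <- NULL
      for (ch in seq_len(nrow(rec$data))) {
        s <- stft_features(rec$data[ch, ], rec$fs, bands = bands,
                           channel = rec$channel_labels[ch])
        vals <- c(vals, s$values)
        meta <- rbind(meta, s$meta)
      }
      list(values = vals, meta = meta)
    },
    emd = {
      if (!is.null(cfg$resample_to) && cfg$resample_to != rec$fs)
        rec <- resample_recording(rec, cfg$resample_to)
      band_tbl <- eeg_bands()
      band_tbl <- band_tbl[band_tbl$band %in% bands, , drop = FALSE]
      vals <- numeric(0); meta <- NULL
      for (ch in seq_len(nrow(rec$data))) {
        im <- emd_sift(rec$data[ch, ])
        low <- rep(0, ncol(rec$data))
        for (k in seq_along(im$imfs)) {
          f0 <- dominant_frequency(im$imfs[[k]], rec$fs)
          if (any(f0 >= band_tbl$low & f0 < band_tbl$high))
            low <- low + im$imfs[[k]]
        }
        vals <- c(vals, low)
        meta <- rbind(meta, data.frame(
          channel = rec$channel_labels[ch], band = "delta+theta",
          block = "imf", index = seq_along(low), stringsAsFactors = FALSE))
      }
      list(values = vals, meta = meta)
    },
    psd = {
      band_tbl <- eeg_bands()
      band_tbl <- band_tbl[band_tbl$high <= 35, , drop = FALSE]
      vals <- numeric(0); meta <- NULL
      for (ch in seq_len(nrow(rec$data))) {
        p <- vapply(seq_len(nrow(band_tbl)), function(b)
          band_power(rec$data[ch, ], rec$fs, band_tbl$low[b],
                     band_tbl$high[b]), numeric(1))
        vals <- c(vals, log10(pmax(p, 1e-12)))
        meta <- rbind(meta, data.frame(
          channel = rec$channel_labels[ch], band = band_tbl$band,
          block = "welch", index = seq_len(nrow(band_tbl)),
          stringsAsFactors = FALSE))
      }
      list(values = vals, meta = meta)
    },
    coherence = {
      co <- coherence_features(rec)
      co$meta$block <- "msc"
      list(values = co$values, meta = co$meta)
    },
    p300 = {
      p3 <- p300_extract(rec)
      list(values = c(p3$p300_amplitude, p3$p300_latency),
           meta = data.frame(
             channel = rep(p3$channel, 2),
             band = rep(c("amplitude", "latency"), each = nrow(p3)),
             block = "p300",
             index = seq_len(2 * nrow(p3)), stringsAsFactors = FALSE))
    })
}

#' Relabel patients for the diagnosis task
#'
#' Collapses `R`/`NR` to `MDD` so patients-versus-controls
#' classification can reuse the same machinery.
#'
#' @param fm a [feature_matrix()].
#' @return The relabeled `feature_matrix`.
#' @export
as_diagnosis_task <- function(fm) {
  fm$instance_meta$group[fm$instance_meta$group %in% c("R", "NR")] <- "MDD"
  fm
}
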