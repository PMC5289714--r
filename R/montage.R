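#' Standard 19-channel 10-20 montage
#'
#' Channel labels of the 19-electrode international 10-20 placement used
#' throughout the package, in the conventional anterior-to-posterior order,
#' together with schematic 2-D head-disc coordinates (x towards the right
#' ear, y towards the nasion, unit head radius) used for topographic
#' interpolation.
#'
#' @return `montage_1020()` returns a character vector of 19 labels;
#'   `montage_coordinates()` returns a data frame with columns `channel`,
#'   `x`, `y`.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' @rdname montage_1020
#' @export
montage_coordinates <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T3", "C3", "Cz", "C4", "T4",
                "T5", "P3", "Pz", "P4", "T6", "O1", "O2"),
    x = c(-0.25, 0.25, -0.65, -0.35, 0, 0.35, 0.65,
          -0.8, -0.4, 0, 0.4, 0.8,
          -0.65, -0.35, 0, 0.35, 0.65, -0.25, 0.25),
    y = c(0.8, 0.8, 0.5, 0.4, 0.4, 0.4, 0.5,
          0, 0, 0, 0, 0,
          -0.5, -0.4, -0.4, -0.4, -0.5, -0.8, -0.8),
    stringsAsFactors = FALSE
  )
}

#' EEG frequency-band definitions
#'
#' The dyadic band edges used for wavelet band mapping and for synthetic
#' band-limited signal generation. At a 140 Hz analysis rate a 5-level
#' dyadic decomposition lands exactly on these edges (70, 35, 17.5, 8.75,
#' 4.375 Hz), which is why recordings are resampled to 140 Hz before the
#' wavelet stage.
#'
#' @return A data frame with columns `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(0.5, 4, 8.5, 17.5, 35),
    high = c(4, 8.5, 17.5, 35, 70),
    stringsAsFactors = FALSE
  )
}
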