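## Daubechies-4 (db4, 8-tap) analysis and synthesis filters.
.db4 <- list(
  dec_lo = c(-0.010597401785069032, 0.032883011666885197,
             0.030841381835560764, -0.18703481171909309,
             -0.027983769416859854, 0.63088076792985892,
             0.71484657055291567, 0.23037781330889651),
  dec_hi = c(-0.23037781330889651, 0.71484657055291567,
             -0.63088076792985892, -0.027983769416859854,
             0.18703481171909309, 0.030841381835560764,
             -0.032883011666885197, -0.010597401785069032),
  rec_lo = c(0.23037781330889651, 0.71484657055291567,
             0.63088076792985892, -0.027983769416859854,
             -0.18703481171909309, 0.030841381835560764,
             0.032883011666885197, -0.010597401785069032),
  rec_hi = c(-0.010597401785069032, -0.032883011666885197,
             0.030841381835560764, 0.18703481171909309,
             -0.027983769416859854, -0.63088076792985892,
             0.71484657055291567, -0.23037781330889651)
)

.wavelet_filters <- function(wavelet) {
  if (!identical(tolower(wavelet), "db4"))
    stop("only the db4 wavelet is implemented")
  .db4
}

# Full linear convolution of every column of X with kernel h,
# vectorized as F shifted matrix accumulations.
.conv_cols <- function(X, h) {
  n <- nrow(X); F_ <- length(h)
  out <- matrix(0, n + F_ - 1, ncol(X))
  for (j in seq_len(F_))
    out[j:(j + n - 1), ] <- out[j:(j + n - 1), ] + h[j] * X
  out
}

# Single-level analysis step with half-point symmetric boundary extension.
# Coefficient length follows floor((n - 1) / 2) + F/2, the convention of
# the standard wavedec tooling with 'sym' extension.
.dwt_step <- function(X, filters) {
  n <- nrow(X); F_ <- length(filters$dec_lo)
  L <- floor((n - 1) / 2) + F_ / 2
  ext <- rbind(X[(F_ - 1):1, , drop = FALSE], X,
               X[n:(n - F_ + 2), , drop = FALSE])
  idx <- seq(F_ + 1, by = 2, length.out = L)
  list(A = .conv_cols(ext, filters$dec_lo)[idx, , drop = FALSE],
       D = .conv_cols(ext, filters$dec_hi)[idx, , drop = FALSE])
}

# Single-level synthesis step; target_len trims the half-sample ambiguity
# (reconstruction length is 2 L - F + 2, one more than needed when the
# parent length was odd).
.idwt_step <- function(A, D, filters, target_len) {
  F_ <- length(filters$rec_lo)
  up <- function(c) { u <- numeric(2 * length(c)); u[seq(1, 2 * length(c), 2)] <- c; u }
  full <- .conv_cols(cbind(up(A)), filters$rec_lo) +
    .conv_cols(cbind(up(D)), filters$rec_hi)
  out <- full[(F_ - 1):(F_ - 2 + 2 * length(A) - F_ + 2), 1]
  out[seq_len(target_len)]
}

#' Multilevel discrete wavelet decomposition (db4)
#'
#' Dyadic filter-bank decomposition with symmetric boundary extension,
#' the workhorse of the wavelet feature family. Coefficient block lengths
#' follow the recurrence `len_k = floor((len_{k-1} - 1) / 2) + 4` for the
#' 8-tap db4 filters. Blocks are returned coarsest first,
#' `[A_L, D_L, ..., D_1]`, and each block is mapped to the EEG band whose
#' dyadic frequency range it covers at the supplied analysis rate. The
#' default depth 4 at 140 Hz produces the five canonical band blocks:
#' A4 = delta (0-4.375 Hz), D4 = theta (4.375-8.75), D3 = alpha + low
#' beta (8.75-17.5), D2 = beta (17.5-35), D1 = gamma (35-70).
#'
#' @param signal numeric vector (or samples-by-signals matrix, decomposed
#'   column-wise).
#' @param wavelet wavelet name; only `"db4"` is implemented.
#' @param levels decomposition depth (default 4, i.e. five band blocks).
#' @param fs sampling rate used for the band map annotation (default 140).
#' @return An object of class `wavelet_decomposition`: list with
#'   `coeff_blocks` (named list, each a vector or matrix), `band_map`
#'   (data frame: block, band, low, high), `lengths` (the per-level
#'   signal-length chain used for exact reconstruction), `wavelet`,
#'   `levels`, `fs`.
#' @export
dwt_decompose <- function(signal, wavelet = "db4", levels = 4, fs = 140) {
  filters <- .wavelet_filters(wavelet)
  F_ <- length(filters$dec_lo)
  X <- if (is.matrix(signal)) signal else matrix(signal, ncol = 1)
  if (nrow(X) <= F_ * 2^levels)
    stop("signal too short for ", levels, " decomposition levels ",
         "(need > ", F_ * 2^levels, " samples)")
  lens <- nrow(X)
  blocks <- vector("list", levels + 1)
  A <- X
  for (k in seq_len(levels)) {
    st <- .dwt_step(A, filters)
    blocks[[levels + 2 - k]] <- .simplify(st$D)
    A <- st$A
    lens <- c(lens, nrow(A))
  }
  blocks[[1]] <- .simplify(A)
  names(blocks) <- c(paste0("A", levels), paste0("D", levels:1))

  # dyadic band edges of each block at the analysis rate
  hi <- fs / 2^(1:levels)
  band_map <- data.frame(
    block = names(blocks),
    low = c(0, hi[levels:1] / 2),
    high = c(hi[levels] / 2, hi[levels:1]),
    stringsAsFactors = FALSE
  )
  band_map$band <- .map_blocks_to_bands(band_map)

  structure(list(coeff_blocks = blocks, band_map = band_map,
                 lengths = lens, wavelet = wavelet, levels = levels,
                 fs = fs),
            class = "wavelet_decomposition")
}

.simplify <- function(M) if (ncol(M) == 1) drop(M) else M

# Assign each dyadic block the EEG band containing its center frequency,
# so the mapping stays correct at any analysis rate whose dyadic grid
# reaches the delta/theta edges (140 Hz/depth 4 and 70 Hz/depth 3 both
# give A = delta 0-4.375 Hz, coarsest D = theta 4.375-8.75 Hz). Blocks
# below the delta floor are labelled "sub-delta", above gamma "supra".
.map_blocks_to_bands <- function(band_map) {
  bands <- eeg_bands()
  centers <- (band_map$low + band_map$high) / 2
  vapply(centers, function(fc) {
    if (fc < bands$low[1] && fc < 0.25) return("sub-delta")
    hit <- which(fc >= bands$low & fc < bands$high)
    if (length(hit) == 1) bands$band[hit]
    else if (fc < bands$low[1]) "delta" else "supra"
  }, character(1))
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  lens <- sapply(x$coeff_blocks, NROW)
  cat(sprintf("<wavelet_decomposition> %s, %d levels @ %g Hz\n",
              x$wavelet, x$levels, x$fs))
  for (i in seq_along(lens))
    cat(sprintf("  %-3s %-9s %6.3f-%6.3f Hz  %d coefficients\n",
                x$band_map$block[i], x$band_map$band[i], x$band_map$low[i],
                x$band_map$high[i], lens[i]))
  invisible(x)
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the original signal from all coefficient blocks; with
#' every block retained the reconstruction is exact to numerical
#' precision. Passing `keep` reconstructs the band-limited component
#' carried by a subset of blocks (the others zeroed).
#'
#' @param dec a [dwt_decompose()] result (single-signal decompositions
#'   only).
#' @param keep optional character vector of block names to retain.
#' @return Numeric vector of the original signal length.
#' @export
dwt_reconstruct <- function(dec, keep = NULL) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  filters <- .wavelet_filters(dec$wavelet)
  blocks <- dec$coeff_blocks
  if (any(sapply(blocks, is.matrix)))
    stop("reconstruction expects a single-signal decomposition")
  if (!is.null(keep))
    for (nm in setdiff(names(blocks), keep))
      blocks[[nm]] <- blocks[[nm]] * 0
  A <- blocks[[1]]
  for (k in seq_len(dec$levels)) {
    target <- dec$lengths[dec$levels + 1 - k]
    A <- .idwt_step(A, blocks[[k + 1]], filters, target)
  }
  A
}

#' Extract per-band wavelet coefficient features
#'
#' Concatenates the coefficient vectors of the requested bands (delta and
#' theta by default; the finer alpha/beta/gamma blocks are discarded from
#' the classification feature set) and tags every coefficient with its
#' channel, band and within-block index.
#'
#' @param dec a [dwt_decompose()] result for one signal.
#' @param bands band names to retain (subset of the decomposition's band
#'   map). An empty set returns a zero-length vector.
#' @param channel channel label recorded in the metadata.
#' @return List with `values` (numeric vector) and `meta` (data frame:
#'   `channel`, `band`, `block`, `index`).
#' @export
band_coefficients <- function(dec, bands = c("delta", "theta"),
                              channel = NA_character_) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  unknown <- setdiff(bands, dec$band_map$band)
  if (length(unknown) > 0)
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  values <- numeric(0)
  meta <- data.frame(channel = character(0), band = character(0),
                     block = character(0), index = integer(0),
                     stringsAsFactors = FALSE)
  for (b in bands) {
    for (blk in dec$band_map$block[dec$band_map$band == b]) {
      v <- dec$coeff_blocks[[blk]]
      values <- c(values, v)
      meta <- rbind(meta, data.frame(
        channel = channel, band = b, block = blk,
        index = seq_along(v), stringsAsFactors = FALSE))
    }
  }
  list(values = values, meta = meta)
}

#' Coefficient-length chain of the db4 decomposition
#'
#' Applies the block-length recurrence `len_k = floor((len_{k-1} - 1) / 2)
#' + 4` without computing any transform; used to predict feature counts.
#'
#' @param n input signal length.
#' @param levels decomposition depth.
#' @return Integer vector of detail/approximation block lengths for
#'   levels `1..levels` (the level-`levels` entry is also the
#'   approximation block length).
#' @export
dwt_block_lengths <- function(n, levels = 4) {
  out <- integer(levels)
  for (k in seq_len(levels)) {
    n <- floor((n - 1) / 2) + 4
    out[k] <- n
  }
  out
}
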