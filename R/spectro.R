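#' Short-time power spectrogram of a recording
#'
#' Standard short-time Fourier power spectrum (Hamming window), the
#' time-frequency grid on which fUSV detection operates. Detection uses
#' `overlap = 0`; display may use 0.5.
#'
#' @param x A [ramp_recording()] or a numeric waveform.
#' @param fs Sampling rate, Hz (ignored when `x` is a recording).
#' @param nfft Window length, samples (power of two). Default 2048.
#' @param overlap Window overlap fraction in \[0, 1). Default 0.
#' @return A list of class `spectrogram_grid` with `times` (bin centres, s),
#'   `freqs` (Hz, 0..fs/2), `power` (time x frequency matrix), `nfft`,
#'   `overlap`, `fs`, and `hop` (samples per time step).
#' @export
usv_spectrogram <- function(x, fs = NULL, nfft = 2048L, overlap = 0) {
  if (inherits(x, "ramp_recording")) {
    fs <- x$fs
    x <- x$sound
  }
  stopifnot(is.numeric(x), !is.null(fs))
  if (nfft < 2 || bitwAnd(nfft, nfft - 1L) != 0) {
    stop("`nfft` must be a power of two", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  if (length(x) < nfft) {
    warning("signal shorter than one window; returning a single zero-padded bin")
    x <- c(x, numeric(nfft - length(x)))
  }
  hop <- as.integer(round(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  win <- signal::hamming(nfft)
  nf <- nfft / 2 + 1
  power <- matrix(0, nrow = length(starts), ncol = nf)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nfft - 1L)] * win
    sp <- stats::fft(seg)[seq_len(nf)]
    power[i, ] <- Re(sp * Conj(sp))
  }
  structure(
    list(
      times = (starts - 1 + nfft / 2) / fs,
      freqs = seq(0, fs / 2, length.out = nf),
      power = power,
      nfft = nfft, overlap = overlap, fs = fs, hop = hop,
      starts = starts
    ),
    class = "spectrogram_grid"
  )
}

in_band_idx <- function(grid, band) {
  idx <- which(grid$freqs >= band[1] & grid$freqs <= band[2])
  if (length(idx) == 0) stop("empty frequency band", call. = FALSE)
  idx
}

#' Scaled Shannon entropy of the in-band power distribution
#'
#' For each spectrogram time bin, the power between `band[1]` and `band[2]`
#' is normalised to a probability distribution `p_i` over frequency bins and
#' its Shannon entropy `H = -sum p_i log2 p_i` is scaled by `log2(nfft/2)`.
#' Tonal whistles concentrate power (entropy near 0); flow-induced
#' turbulence noise spreads it (entropy near 1). Bins with zero in-band
#' power are assigned entropy 1 (maximally noise-like), so silence is never
#' detected as a fUSV.
#'
#' @param grid A `spectrogram_grid` from [usv_spectrogram()].
#' @param band Analysis band, Hz. Default 15--100 kHz.
#' @param denominator `"half"` scales by `log2(nfft/2)` (default);
#'   `"squared_half"` by `log2(nfft^2/2)`.
#' @return Numeric vector of per-bin scaled entropies in \[0, 1\].
#' @export
scaled_entropy <- function(grid, band = c(15e3, 100e3),
                           denominator = c("half", "squared_half")) {
  stopifnot(inherits(grid, "spectrogram_grid"))
  denominator <- match.arg(denominator)
  idx <- in_band_idx(grid, band)
  P <- grid$power[, idx, drop = FALSE]
  tot <- rowSums(P)
  denom <- switch(denominator,
                  half = log2(grid$nfft / 2),
                  squared_half = log2(grid$nfft^2 / 2))
  H <- vapply(seq_len(nrow(P)), function(i) {
    if (tot[i] <= 0) return(denom) # all-zero bin: maximally noise-like
    p <- P[i, ] / tot[i]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  pmin(H / denom, 1)
}

#' Aggregate per-bin values into time slices
#'
#' Entropy (and other per-bin series) is smoothed by arithmetic averaging
#' over fixed groups of spectrogram bins: 6 bins per slice for rats, 3 for
#' mice. A trailing partial slice is dropped.
#'
#' @param x Per-bin numeric vector.
#' @param slice_size Bins per slice.
#' @return Per-slice means.
#' @export
slice_means <- function(x, slice_size) {
  stopifnot(slice_size >= 1)
  ns <- length(x) %/% slice_size
  if (ns == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(ns * slice_size)], nrow = slice_size))
}

#' Detection threshold from noise entropy
#'
#' The fUSV detection threshold is derived from ramps with an unadducted
#' glottis (noise only): the mean minus two standard deviations of the
#' scaled entropy during maximum flow. For rats this procedure yields 0.7,
#' used for all other ramps; for mice a signal-based 0.8 is used instead
#' (see [species_preset()]).
#'
#' @param noise_entropy Per-bin scaled entropies during maximum flow
#'   (at least 10 samples), or `NULL` to fall back to the species preset.
#' @param species Species preset used for the fallback.
#' @return Threshold (scalar).
#' @export
derive_threshold <- function(noise_entropy = NULL, species = c("rat", "mouse")) {
  species <- match.arg(species)
  if (is.null(noise_entropy)) {
    return(species_preset(species)$threshold)
  }
  if (length(noise_entropy) < 10) {
    stop("need at least 10 noise entropy samples to derive a threshold",
         call. = FALSE)
  }
  mean(noise_entropy) - 2 * sd(noise_entropy)
}
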