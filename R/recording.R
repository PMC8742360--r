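#' A time-aligned multichannel excised-larynx recording
#'
#' Bundles the three channels measured during a pressure-ramp experiment:
#' received sound (Pa), tracheal pressure (kPa) and tracheal mass flow
#' (ml/s), sharing one sampling rate.
#'
#' @param sound Sound pressure waveform, Pa.
#' @param pressure Tracheal pressure waveform, kPa (same length).
#' @param flow Tracheal flow waveform, ml/s (same length).
#' @param fs Sampling rate, Hz.
#' @param species Species preset, `"rat"` or `"mouse"`; sets the entropy
#'   slice size (6 or 3 spectrogram bins) and fallback detection threshold
#'   (0.7 or 0.8).
#' @return A list of class `ramp_recording`.
#' @export
ramp_recording <- function(sound, pressure, flow, fs, species = c("rat", "mouse")) {
  species <- match.arg(species)
  if (length(sound) != length(pressure) || length(sound) != length(flow)) {
    stop("sound, pressure and flow channels must share length", call. = FALSE)
  }
  if (length(sound) == 0) stop("channels must be nonempty", call. = FALSE)
  stopifnot(fs > 0)
  structure(
    list(sound = as.numeric(sound), pressure = as.numeric(pressure),
         flow = as.numeric(flow), fs = fs, species = species),
    class = "ramp_recording"
  )
}

#' @export
print.ramp_recording <- function(x, ...) {
  cat(sprintf(
    "Ramp recording (%s): %.2f s at %g kHz; peak pressure %.2f kPa, peak flow %.2f ml/s\n",
    x$species, length(x$sound) / x$fs, x$fs / 1e3, max(x$pressure), max(x$flow)))
  invisible(x)
}

#' Species presets for fUSV detection
#'
#' @param species `"rat"` or `"mouse"`.
#' @return List with `slice_size` (spectrogram bins per entropy slice) and
#'   `threshold` (fallback scaled-entropy detection threshold).
#' @export
species_preset <- function(species = c("rat", "mouse")) {
  species <- match.arg(species)
  switch(species,
    rat   = list(slice_size = 6L, threshold = 0.7),
    mouse = list(slice_size = 3L, threshold = 0.8)
  )
}

#' Condition a raw recording for fUSV analysis
#'
#' Resamples all channels to `target_fs` (default 240 kHz) with a polyphase
#' antialiasing filter and band-passes the sound channel 2.5--100 kHz with a
#' 3rd-order Butterworth applied forward-backward (zero phase, effective
#' order 6). Pressure and flow are resampled but not band-passed (they are
#' slow channels).
#'
#' @param rec A [ramp_recording()].
#' @param target_fs Target sampling rate, Hz. Default 240000.
#' @param band Passband for the sound channel, Hz. Default `c(2500, 1e5)`.
#' @return A conditioned [ramp_recording()].
#' @export
condition_recording <- function(rec, target_fs = 240e3, band = c(2500, 1e5)) {
  stopifnot(inherits(rec, "ramp_recording"))
  if (rec$fs < 2 * band[2]) {
    warning(sprintf(
      "sampling rate %g Hz cannot carry the full %g kHz band; upper band edge truncated",
      rec$fs, band[2] / 1e3))
    band[2] <- min(band[2], 0.95 * rec$fs / 2)
  }
  resamp <- function(x) {
    if (rec$fs == target_fs) return(x)
    r <- ratio_pq(target_fs, rec$fs)
    as.numeric(signal::resample(x, r$p, r$q))
  }
  sound <- resamp(rec$sound)
  pressure <- resamp(rec$pressure)
  flow <- resamp(rec$flow)
  n <- min(length(sound), length(pressure), length(flow))
  bf <- signal::butter(3, c(band[1], min(band[2], 0.999 * target_fs / 2)) /
                            (target_fs / 2), type = "pass")
  sound <- as.numeric(signal::filtfilt(bf, sound[seq_len(n)]))
  ramp_recording(sound, pressure[seq_len(n)], flow[seq_len(n)],
                 fs = target_fs, species = rec$species)
}

# Small integer resampling ratio p/q = to/from.
ratio_pq <- function(to, from) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(to), round(from))
  list(p = round(to) / d, q = round(from) / d)
}
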