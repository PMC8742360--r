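#' Detect fictive USVs from a slice entropy series
#'
#' A fUSV is a period of tonal sound: a maximal run of time slices with
#' scaled entropy below the threshold, at least two slices long, where a
#' single above-threshold slice inside a run does not split it (breaks of
#' one slice are allowed). Runs containing a single below-threshold slice
#' are discarded.
#'
#' @param slice_entropy Per-slice scaled entropies (see [slice_means()]).
#' @param threshold Detection threshold (see [derive_threshold()]).
#' @return A data frame with one row per segment: `segment_id`,
#'   `start_slice`, `end_slice` (1-based, inclusive), `n_below`. Zero rows
#'   when nothing is detected.
#' @export
#' @examples
#' detect_fusv(c(0.9, 0.6, 0.6, 0.9), 0.7) # one segment, slices 2-3
#' detect_fusv(c(0.6, 0.8, 0.6), 0.7)      # one-slice gap bridged
detect_fusv <- function(slice_entropy, threshold) {
  below <- which(slice_entropy < threshold)
  if (length(below) == 0) {
    return(data.frame(segment_id = integer(0), start_slice = integer(0),
                      end_slice = integer(0), n_below = integer(0)))
  }
  # gaps of one above-threshold slice (diff == 2) do not split a run
  grp <- cumsum(c(1, diff(below) > 2))
  runs <- split(below, grp)
  runs <- runs[vapply(runs, length, integer(1)) >= 2]
  if (length(runs) == 0) {
    return(data.frame(segment_id = integer(0), start_slice = integer(0),
                      end_slice = integer(0), n_below = integer(0)))
  }
  data.frame(
    segment_id = seq_along(runs),
    start_slice = vapply(runs, min, integer(1)),
    end_slice = vapply(runs, max, integer(1)),
    n_below = vapply(runs, length, integer(1)),
    row.names = NULL
  )
}

#' Extract the peak-frequency ridge through a spectrogram segment
#'
#' Finds the maximum-energy ridge through the in-band spectrogram by dynamic
#' programming: the path maximising summed log power minus
#' `jump_penalty * (delta_bin)^2` between consecutive time bins. This is the
#' time-frequency ridge that tracks the whistle's dominant frequency.
#'
#' @param grid A `spectrogram_grid`.
#' @param bins Time-bin indices to track over (e.g. a detected segment's
#'   bins). Default all.
#' @param band Frequency band, Hz. Default 15--100 kHz.
#' @param jump_penalty Penalty per squared bin jump, in log-power units.
#'   Default 0.05.
#' @param max_jump Largest allowed frequency-bin jump per time step.
#'   Default 40.
#' @return Numeric vector of ridge frequencies, Hz (one per requested bin).
#' @export
extract_ridge <- function(grid, bins = seq_along(grid$times),
                          band = c(15e3, 100e3), jump_penalty = 0.05,
                          max_jump = 40L) {
  stopifnot(inherits(grid, "spectrogram_grid"))
  fidx <- in_band_idx(grid, band)
  P <- grid$power[bins, fidx, drop = FALSE]
  if (all(P <= 0)) stop("all-zero power in segment: ridge undefined", call. = FALSE)
  nt <- nrow(P); nf <- ncol(P)
  eps <- max(P) * 1e-12
  L <- log(P + eps)
  score <- L[1, ]
  back <- matrix(0L, nt, nf)
  offs <- seq(-max_jump, max_jump)
  pen <- jump_penalty * offs^2
  for (t in seq_len(nt)[-1]) {
    best <- rep(-Inf, nf)
    arg <- integer(nf)
    for (k in seq_along(offs)) {
      o <- offs[k]
      # previous bin j - o feeds bin j
      src <- seq_len(nf) - o
      valid <- src >= 1 & src <= nf
      cand <- rep(-Inf, nf)
      cand[valid] <- score[src[valid]] - pen[k]
      better <- cand > best
      best[better] <- cand[better]
      arg[better] <- src[better]
    }
    score <- best + L[t, ]
    back[t, ] <- arg
  }
  path <- integer(nt)
  path[nt] <- which.max(score)
  if (nt > 1) {
    for (t in rev(seq_len(nt - 1))) path[t] <- back[t + 1, path[t + 1]]
  }
  grid$freqs[fidx[path]]
}

#' Per-slice features of a detected fUSV segment
#'
#' For each time slice of a detected segment, extracts the peak frequency
#' (mean ridge frequency over the slice's spectrogram bins), the arithmetic
#' mean of flow and pressure over the slice's samples, and the RMS of the
#' sound channel.
#'
#' @param rec A conditioned [ramp_recording()].
#' @param grid The `spectrogram_grid` of `rec` (overlap 0).
#' @param segment One row of the [detect_fusv()] output.
#' @param slice_size Spectrogram bins per slice.
#' @param band Analysis band, Hz.
#' @param jump_penalty Passed to [extract_ridge()].
#' @return A data frame with one row per slice: `slice_index`, `t_start_s`,
#'   `t_end_s`, `f_p_kHz`, `flow_ml_s`, `pressure_kPa`, `rms_Pa`.
#' @export
segment_features <- function(rec, grid, segment, slice_size,
                             band = c(15e3, 100e3), jump_penalty = 0.05) {
  stopifnot(inherits(rec, "ramp_recording"), inherits(grid, "spectrogram_grid"))
  slices <- segment$start_slice:segment$end_slice
  bin_of_slice <- lapply(slices, function(s) ((s - 1L) * slice_size + 1L):(s * slice_size))
  bins <- unlist(bin_of_slice)
  if (max(bins) > length(grid$times)) stop("segment outside grid time range", call. = FALSE)
  ridge <- extract_ridge(grid, bins = bins, band = band, jump_penalty = jump_penalty)
  out <- lapply(seq_along(slices), function(i) {
    b <- bin_of_slice[[i]]
    local_idx <- match(b, bins)
    s0 <- grid$starts[b[1]]
    s1 <- grid$starts[b[length(b)]] + grid$nfft - 1L
    samp <- s0:min(s1, length(rec$sound))
    data.frame(
      slice_index = slices[i],
      t_start_s = (s0 - 1) / rec$fs,
      t_end_s = s1 / rec$fs,
      f_p_kHz = mean(ridge[local_idx]) / 1e3,
      flow_ml_s = mean(rec$flow[samp]),
      pressure_kPa = mean(rec$pressure[samp]),
      rms_Pa = sqrt(mean(rec$sound[samp]^2))
    )
  })
  do.call(rbind, out)
}

#' Full fUSV detection pipeline on a conditioned recording
#'
#' Runs spectrogram, scaled entropy, slice aggregation, threshold detection,
#' ridge extraction and feature extraction, returning the per-slice segments
#' table.
#'
#' @param rec A conditioned [ramp_recording()].
#' @param threshold Detection threshold; `NULL` uses the species preset.
#' @param nfft,overlap Spectrogram parameters (detection uses overlap 0).
#' @param band Analysis band, Hz.
#' @param jump_penalty Ridge tracker penalty.
#' @return A list with `segments` (table with columns `segment_id`,
#'   `slice_index`, `t_start_s`, `t_end_s`, `f_p_kHz`, `flow_ml_s`,
#'   `pressure_kPa`, `rms_Pa`), `slice_entropy`, `threshold`, `grid` and
#'   `slice_size`.
#' @export
detect_fusv_recording <- function(rec, threshold = NULL, nfft = 2048L,
                                  overlap = 0, band = c(15e3, 100e3),
                                  jump_penalty = 0.05) {
  stopifnot(inherits(rec, "ramp_recording"))
  preset <- species_preset(rec$species)
  if (is.null(threshold)) threshold <- preset$threshold
  grid <- usv_spectrogram(rec, nfft = nfft, overlap = overlap)
  ent <- scaled_entropy(grid, band = band)
  sl_ent <- slice_means(ent, preset$slice_size)
  segs <- detect_fusv(sl_ent, threshold)
  if (nrow(segs) == 0) {
    segments <- data.frame(segment_id = integer(0), slice_index = integer(0),
                           t_start_s = numeric(0), t_end_s = numeric(0),
                           f_p_kHz = numeric(0), flow_ml_s = numeric(0),
                           pressure_kPa = numeric(0), rms_Pa = numeric(0))
  } else {
    segments <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      feats <- segment_features(rec, grid, segs[i, ], preset$slice_size,
                                band = band, jump_penalty = jump_penalty)
      cbind(segment_id = segs$segment_id[i], feats)
    }))
  }
  list(segments = segments, slice_entropy = sl_ent, threshold = threshold,
       grid = grid, slice_size = preset$slice_size)
}
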