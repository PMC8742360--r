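# CSV and sidecar I/O binding the pipeline modules together. All tables are
# comma-separated UTF-8 with a mandatory header row and '.' decimals; times
# are seconds from recording start, intervals half-open [start, end).

#' Write / read a detected-segments table
#'
#' Columns: `segment_id`, `slice_index`, `t_start_s`, `t_end_s`, `f_p_kHz`,
#' `flow_ml_s`, `pressure_kPa`, `rms_Pa`.
#'
#' @param segments Segments data frame (see [detect_fusv_recording()]).
#' @param path File path.
#' @return `read_segments()` returns the data frame; writers return `path`
#'   invisibly.
#' @export
write_segments <- function(segments, path) {
  write.csv(segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  read.csv(path)
}

#' Write / read a gesture trajectory as CSV
#'
#' Columns: `time_s`, `RM`, `CT`, `TA`, `PCA_IA`.
#'
#' @param gesture A `gesture_trajectory` or activations data frame.
#' @param path File path.
#' @return `read_gesture()` returns a data frame; the writer returns `path`
#'   invisibly.
#' @export
write_gesture <- function(gesture, path) {
  act <- if (inherits(gesture, "gesture_trajectory")) gesture$activations else gesture
  write.csv(act[, intersect(c("time_s", "RM", "CT", "TA", "PCA_IA", "feasible"),
                            names(act))], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gesture
#' @export
read_gesture <- function(path) {
  read.csv(path)
}

#' Write / read frequency + pressure target traces as CSV
#'
#' Columns: `time_s`, `f_kHz`, `p_kPa`.
#'
#' @param trace Data frame with columns `time_s`, `f_kHz`, `p_kPa`.
#' @param path File path.
#' @return `read_trace()` returns a data frame; the writer returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "f_kHz", "p_kPa") %in% names(trace)))
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- read.csv(path)
  if (!all(c("time_s", "f_kHz", "p_kPa") %in% names(tr))) {
    stop("trace CSV must carry columns time_s, f_kHz, p_kPa", call. = FALSE)
  }
  tr
}

#' Write a synthetic ramp to WAV + CSV + YAML sidecars
#'
#' Persists a [generate_ramp()] result as a deterministic fixture triplet:
#' the sound channel as float32 WAV, the auxiliary channels as CSV
#' (`time_s`, `pressure_kPa`, `flow_ml_s`), and a YAML sidecar holding the
#' sampling rate, species, channel units and ground-truth whistle intervals.
#'
#' @param ramp A [generate_ramp()] result.
#' @param stem Output path stem; writes `<stem>.wav`, `<stem>_aux.csv`,
#'   `<stem>.yml`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_ramp <- function(ramp, stem) {
  rec <- ramp$recording
  wav <- paste0(stem, ".wav")
  aux <- paste0(stem, "_aux.csv")
  yml <- paste0(stem, ".yml")
  write_wav(rec$sound, rec$fs, wav)
  t <- (seq_along(rec$pressure) - 1) / rec$fs
  write.csv(data.frame(time_s = t, pressure_kPa = rec$pressure,
                       flow_ml_s = rec$flow), aux, row.names = FALSE)
  yaml::write_yaml(list(
    fs = rec$fs, species = rec$species,
    units = list(sound = "Pa", pressure = "kPa", flow = "ml/s"),
    truth = list(
      intervals = lapply(seq_len(nrow(ramp$truth$intervals)), function(i) {
        as.list(ramp$truth$intervals[i, ])
      }),
      modes = as.list(ramp$truth$modes),
      x_mm = ramp$truth$x_mm, A_gl_mm2 = ramp$truth$A_gl_mm2
    )
  ), yml)
  invisible(c(wav, aux, yml))
}

#' Read a ramp recording from WAV + CSV + YAML sidecars
#'
#' Inverse of [write_ramp()] for the recording part; the sidecar is
#' mandatory because WAV carries no units or species information.
#'
#' @param stem Path stem as in [write_ramp()].
#' @return A [ramp_recording()].
#' @export
read_ramp <- function(stem) {
  yml <- paste0(stem, ".yml")
  if (!file.exists(yml)) {
    stop("missing sidecar with units/species: ", yml, call. = FALSE)
  }
  meta <- yaml::read_yaml(yml)
  wav <- read_wav(paste0(stem, ".wav"))
  aux <- read.csv(paste0(stem, "_aux.csv"))
  n <- min(nrow(wav$data), nrow(aux))
  ramp_recording(wav$data[seq_len(n), 1], aux$pressure_kPa[seq_len(n)],
                 aux$flow_ml_s[seq_len(n)], fs = meta$fs,
                 species = meta$species)
}
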