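# Ground-truthed synthetic data emulating the excised-larynx experiments:
# pressure ramps driving an adducted larynx whose cartilaginous glottis
# whistles by wall impingement, with flow-scaled turbulence noise.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic pressure-ramp recording
#'
#' Describes one synthetic excised-larynx experiment: a piecewise-linear
#' pressure ramp (0 up to `p_peak` and back at `ramp_rate`), orifice-law
#' flow through the adducted (cartilaginous-only) glottis, a
#' wall-impingement whistle active above the phonation threshold while the
#' Strouhal stability criterion holds, and white turbulence noise whose
#' amplitude scales with instantaneous flow, band-limited to 100 kHz.
#'
#' @param ramp_rate Pressure ramp rate, kPa/s (experimental presets 0.5 and
#'   1.66). Default 1.66.
#' @param p_peak Peak ramp pressure, kPa (1.5--2.0 in the experiments).
#'   Default 1.5.
#' @param phonation_threshold Minimum pressure producing sound, kPa.
#'   Default 0.8.
#' @param geometry A [laryngeal_geometry()]; the whistle length is the
#'   geometry's anatomical wall length `x_wall_anat` and the constriction is
#'   the cartilaginous glottis `A_cmax`.
#' @param noise_gain Turbulence noise amplitude, Pa per (ml/s). Default 0.02.
#' @param whistle_amplitude Whistle tone amplitude, Pa. Default 0.1.
#' @param modes_present Integer set of whistle modes synthesised. Default 1.
#' @param fs Sampling rate, Hz. Default 240000.
#' @param seed Integer; fully determines the output.
#' @return A list of class `ramp_spec`.
#' @export
ramp_spec <- function(ramp_rate = 1.66, p_peak = 1.5, phonation_threshold = 0.8,
                      geometry = default_rat_geometry(), noise_gain = 0.02,
                      whistle_amplitude = 0.1, modes_present = 1L,
                      fs = 240e3, seed = 1L) {
  stopifnot(ramp_rate > 0, p_peak > phonation_threshold, phonation_threshold > 0,
            inherits(geometry, "laryngeal_geometry"), noise_gain >= 0,
            whistle_amplitude >= 0, all(modes_present >= 1), fs > 0)
  structure(
    list(ramp_rate = ramp_rate, p_peak = p_peak,
         phonation_threshold = phonation_threshold, geometry = geometry,
         noise_gain = noise_gain, whistle_amplitude = whistle_amplitude,
         modes_present = sort(unique(as.integer(modes_present))),
         fs = fs, seed = as.integer(seed)),
    class = "ramp_spec"
  )
}

#' Generate a synthetic pressure-ramp recording with ground truth
#'
#' Synthesises the recording described by a [ramp_spec()]: pressure follows
#' the up-down ramp, flow follows the orifice law, and the sound channel is
#' the sum of the whistle modes (phase-continuous tones at `n * u(t) / x`)
#' -- active only above the phonation threshold while the whistle is stable
#' -- plus Gaussian noise of standard deviation `noise_gain * flow(t)`
#' low-passed at 100 kHz. Whistle on/offsets carry a one-spectrogram-bin
#' raised-cosine fade to avoid clicks.
#'
#' @param spec A [ramp_spec()].
#' @return A list with `recording` (a [ramp_recording()]) and `truth`
#'   (list: `active` logical per sample, `f1_kHz` instantaneous first-mode
#'   frequency per sample, `intervals` data frame of whistle intervals in
#'   seconds, `modes`, `pressure_kPa`, `flow_ml_s`).
#' @export
generate_ramp <- function(spec) {
  stopifnot(inherits(spec, "ramp_spec"))
  geom <- spec$geometry
  x_mm <- geom$x_wall_anat
  if (!is.finite(x_mm) || x_mm <= 0) {
    stop("geometry must carry an anatomical wall length `x_wall_anat`", call. = FALSE)
  }
  A_gl <- geom$A_cmax
  fs <- spec$fs
  dur <- 2 * spec$p_peak / spec$ramp_rate
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1) / fs
  p <- ifelse(t <= dur / 2, spec$ramp_rate * t,
              pmax(0, spec$p_peak - spec$ramp_rate * (t - dur / 2)))
  V <- orifice_flow(p, A_gl, geom)
  u <- jet_exit_speed(V, A_gl)
  f1 <- u / (x_mm * 1e-3) # Hz
  f_max <- max(spec$modes_present) * max(f1)
  if (fs < 2 * f_max) {
    stop(sprintf("fs = %g Hz cannot carry mode frequencies up to %.0f Hz",
                 fs, f_max), call. = FALSE)
  }
  d <- jet_diameter(A_gl)
  active <- p >= spec$phonation_threshold & (d < x_mm)
  # one-spectrogram-bin raised-cosine fade at on/offsets
  fade_n <- 2048L
  env <- gate_envelope(active, fade_n)

  sound <- numeric(n)
  if (spec$whistle_amplitude > 0) {
    for (nn in spec$modes_present) {
      if (nn >= x_mm / d) next # unstable mode never sounds
      phase <- 2 * pi * cumsum(nn * f1) / fs
      sound <- sound + spec$whistle_amplitude * sin(phase) * env
    }
  }
  noise <- with_seed(spec$seed, rnorm(n)) * spec$noise_gain * V
  if (spec$noise_gain > 0) {
    lp <- signal::butter(4, min(100e3, 0.45 * fs) / (fs / 2), type = "low")
    noise <- as.numeric(signal::filtfilt(lp, noise))
  }
  sound <- sound + noise
  rec <- ramp_recording(sound, p, V, fs = fs, species = "rat")
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(t_start_s = t[starts[runs$values]],
                   t_end_s = t[ends[runs$values]])
  list(
    recording = rec,
    truth = list(active = active, f1_kHz = f1 / 1e3, intervals = iv,
                 modes = spec$modes_present[spec$modes_present < x_mm / d],
                 pressure_kPa = p, flow_ml_s = V, x_mm = x_mm, A_gl_mm2 = A_gl)
  )
}

# Raised-cosine gate: 0/1 per sample with `fade_n`-sample cosine ramps
# inside each active interval.
gate_envelope <- function(active, fade_n) {
  env <- as.numeric(active)
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ramp <- 0.5 * (1 - cos(pi * seq_len(fade_n) / fade_n))
  for (i in which(runs$values)) {
    len <- runs$lengths[i]
    k <- min(fade_n, floor(len / 2))
    if (k < 2) next
    env[starts[i]:(starts[i] + k - 1L)] <- ramp[seq_len(k)]
    env[(ends[i] - k + 1L):ends[i]] <- rev(ramp[seq_len(k)])
  }
  env
}

#' Generate a stationary multi-mode whistle clip
#'
#' A clip holding several simultaneous whistle modes at fixed first-mode
#' frequency, for exercising mode identification: the dominant mode has
#' unit amplitude, the others `side_amplitude`.
#'
#' @param f_1 First-mode frequency, kHz.
#' @param modes Integer set of modes present.
#' @param dominant Which mode carries the most energy. Default lowest.
#' @param duration Clip length, s. Default 0.5.
#' @param fs Sampling rate, Hz. Default 240000.
#' @param side_amplitude Relative amplitude of non-dominant modes. Default 0.4.
#' @param noise_sd White-noise floor. Default 0.001.
#' @param seed Integer seed.
#' @return A list with `sound`, `fs`, and `truth` (list: `f_1_kHz`, `modes`,
#'   `dominant`, `f_p_kHz`).
#' @export
generate_multimode_clip <- function(f_1, modes, dominant = min(modes),
                                    duration = 0.5, fs = 240e3,
                                    side_amplitude = 0.4, noise_sd = 0.001,
                                    seed = 1L) {
  modes <- sort(unique(as.integer(modes)))
  stopifnot(all(modes >= 1), dominant %in% modes, f_1 > 0, duration >= 0)
  if (max(modes) * f_1 * 1e3 >= fs / 2) {
    stop("fs too low for the requested modes (aliasing)", call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  sound <- numeric(n)
  for (nn in modes) {
    amp <- if (nn == dominant) 1 else side_amplitude
    sound <- sound + amp * sin(2 * pi * nn * f_1 * 1e3 * t)
  }
  if (noise_sd > 0 && n > 0) sound <- sound + with_seed(seed, rnorm(n, sd = noise_sd))
  list(sound = sound, fs = fs,
       truth = list(f_1_kHz = f_1, modes = modes, dominant = dominant,
                    f_p_kHz = dominant * f_1))
}

#' Attainable first-mode frequency range at a given pressure
#'
#' Scans the (TA, CT) activation plane (PCA.IA coupled to TA) at a fixed
#' subglottal pressure and returns the range of stable first-mode
#' frequencies the motor model can produce.
#'
#' @param p_kPa Subglottal pressure, kPa.
#' @param geom A [laryngeal_geometry()].
#' @param grid_n Grid points per axis. Default 101.
#' @return `c(min, max)` in kHz, or `c(NA, NA)` if no stable state exists.
#' @export
attainable_f1_range <- function(p_kPa, geom = default_rat_geometry(),
                                grid_n = 101L) {
  ax <- seq(0, 1, length.out = grid_n)
  A_ta <- glottal_area(ax, ax, geom)
  d_ta <- jet_diameter(A_ta)
  u_ta <- ifelse(A_ta > 0,
                 geom$Cd * sqrt(2 * p_kPa * 1e3 / RHO_AIR) /
                   sqrt(1 - (A_ta / geom$A_trachea)^2), 0)
  x <- outer(ax, ax, function(TA, CT) {
    pmax(geom$x_min + (CT - 0.24 * TA) * (geom$x_max - geom$x_min), 0)
  })
  stable <- x > 0 & outer(d_ta, rep(1, grid_n)) < x & u_ta > 0
  f <- outer(u_ta, rep(1, grid_n)) / x
  f[!stable] <- NA
  if (all(is.na(f))) return(c(NA_real_, NA_real_))
  range(f, na.rm = TRUE)
}

#' Generate call-type target traces for gesture inversion
#'
#' Frequency + subglottal-pressure target traces emulating common rat USV
#' call types: `flat22` (constant 22 kHz, low pressure), `step50` (50 kHz
#' call with discrete frequency steps) and `trill50` (50 kHz carrier with
#' sinusoidal modulation, default +/-5 kHz at 60 Hz). Pressures stay within
#' the 3 kPa in vivo cap and every sample is verified feasible under the
#' geometry at generation time.
#'
#' @param call_type `"flat22"`, `"step50"` or `"trill50"`.
#' @param duration Call length, s. Default 0.2.
#' @param dt Sample interval, s. Default 0.001.
#' @param geom A [laryngeal_geometry()].
#' @param trill_depth_kHz,trill_rate_Hz Trill modulation parameters.
#' @param seed Integer seed (reserved; the targets are deterministic).
#' @return A data frame with columns `time_s`, `f_kHz`, `p_kPa`.
#' @export
generate_call_targets <- function(call_type = c("flat22", "step50", "trill50"),
                                  duration = 0.2, dt = 1e-3,
                                  geom = default_rat_geometry(),
                                  trill_depth_kHz = 5, trill_rate_Hz = 60,
                                  seed = 1L) {
  call_type <- match.arg(call_type)
  n <- round(duration / dt)
  if (n == 0) {
    return(data.frame(time_s = numeric(0), f_kHz = numeric(0), p_kPa = numeric(0)))
  }
  t <- (seq_len(n) - 1) * dt
  out <- switch(call_type,
    flat22 = data.frame(time_s = t, f_kHz = rep(22, n), p_kPa = rep(0.65, n)),
    step50 = {
      steps <- c(45, 55, 50)
      f <- steps[pmin(length(steps), 1 + floor(3 * t / duration))]
      data.frame(time_s = t, f_kHz = f, p_kPa = rep(1.8, n))
    },
    trill50 = data.frame(
      time_s = t,
      f_kHz = 50 + trill_depth_kHz * sin(2 * pi * trill_rate_Hz * t),
      p_kPa = rep(1.8, n)
    )
  )
  bad <- vapply(seq_len(n), function(i) {
    r <- attainable_f1_range(out$p_kPa[i], geom)
    is.na(r[1]) || out$f_kHz[i] < r[1] || out$f_kHz[i] > r[2]
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("target infeasible under this geometry at samples: %s",
                 paste(head(which(bad), 10), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Generate a smooth synthetic motor gesture
#'
#' A smooth activation trajectory for round-trip testing of the inversion:
#' TA held at a fixed adduction level, CT a raised-cosine sweep, RM a gentle
#' pressure ramp. All traces stay well inside the activation bounds and the
#' whistle remains stable throughout.
#'
#' @param duration Gesture length, s. Default 0.2.
#' @param dt Sample interval, s. Default 0.001.
#' @param TA_level Constant TA activation. Default 0.6.
#' @param CT_range CT sweep range. Default `c(0.30, 0.45)`.
#' @param RM_range RM sweep range. Default `c(0.25, 0.35)`.
#' @return A data frame with columns `time_s`, `RM`, `CT`, `TA`, `PCA_IA`.
#' @export
generate_smooth_gesture <- function(duration = 0.2, dt = 1e-3, TA_level = 0.6,
                                    CT_range = c(0.30, 0.45),
                                    RM_range = c(0.25, 0.35)) {
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  s <- 0.5 * (1 - cos(2 * pi * t / duration))  # 0 -> 1 -> 0, smooth
  data.frame(
    time_s = t,
    RM = RM_range[1] + (RM_range[2] - RM_range[1]) * s,
    CT = CT_range[1] + (CT_range[2] - CT_range[1]) * s,
    TA = rep(TA_level, n),
    PCA_IA = rep(TA_level, n)
  )
}
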