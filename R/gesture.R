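#' Recover a motor gesture from frequency and pressure traces
#'
#' Inverts the embodied motor map: given a whistle frequency trace and the
#' corresponding subglottal pressure trace, finds a smooth trajectory of
#' muscle activations that reproduces them. RM follows directly from
#' pressure (`RM = p_t / p_max`). The laryngeal pair (TA, CT) is found by a
#' dense grid search over \[0, 1\]^2 restricted to states whose lowest
#' stable mode matches the target frequency within `tol_kHz`; among feasible
#' cells the one minimising the squared activation step from the previous
#' sample is chosen. PCA.IA is coupled to TA.
#'
#' Frequency alone leaves the laryngeal state redundant along a
#' near-linear ridge in (TA, CT) (jet speed barely depends on glottal area),
#' so the first sample anchors the trajectory: by default the
#' minimal-activation-norm feasible cell, or `init` when a starting posture
#' is known. Samples with an empty feasible set are flagged infeasible and
#' linearly interpolated across runs of at most `max_gap` samples.
#'
#' @param f_trace Target frequency trace, kHz (NA = no whistle at that sample).
#' @param p_trace Subglottal pressure trace, kPa, same length.
#' @param geom A [laryngeal_geometry()].
#' @param tol_kHz Frequency matching tolerance, kHz. Default 0.5.
#' @param grid_n Grid points per activation axis. Default 201.
#' @param init Optional `c(TA, CT)` anchor for the first feasible sample.
#' @param max_gap Maximum run of infeasible samples to interpolate. Default 3.
#' @param ta_step_weight Relative penalty on TA steps in the step metric.
#'   TA barely affects frequency (it mainly gates whistle stability), so
#'   frequency tracking is attributed to CT by weighting TA moves more
#'   heavily; 1 gives the isotropic metric. Default 4.
#' @param smooth_bound Maximum activation step per 10 ms flagged as smooth.
#'   Default 0.1.
#' @param times Optional time stamps (s); default 1 ms sampling.
#' @return A list of class `gesture_trajectory`: data frame `activations`
#'   (time_s, RM, CT, TA, PCA_IA, feasible), the realised per-sample motor
#'   `states`, achieved `f_kHz`, and `smoothness_violations`
#'   (sample indices exceeding `smooth_bound`).
#' @export
invert_gesture <- function(f_trace, p_trace, geom = default_rat_geometry(),
                           tol_kHz = 0.5, grid_n = 201L, init = NULL,
                           max_gap = 3L, ta_step_weight = 4, smooth_bound = 0.1,
                           times = NULL) {
  stopifnot(length(f_trace) == length(p_trace), length(f_trace) >= 1L)
  if (any(p_trace < 0 | p_trace > geom$p_max)) {
    stop("pressure trace outside [0, p_max]", call. = FALSE)
  }
  nt <- length(f_trace)
  if (is.null(times)) times <- (seq_len(nt) - 1L) * 1e-3
  ax <- seq(0, 1, length.out = grid_n)

  # grid quantities independent of pressure: area/diameter depend on TA only
  # (coupled PCA.IA), impingement length on (TA, CT)
  A_ta <- glottal_area(ax, ax, geom)                 # by TA index
  d_ta <- jet_diameter(A_ta)
  beta2 <- (A_ta / geom$A_trachea)^2
  # u = Cd * sqrt(2 p / rho) / sqrt(1 - beta^2); the TA-dependent factor:
  u_factor <- geom$Cd / sqrt(1 - beta2)              # by TA index
  x_grid <- outer(ax, ax, function(TA, CT) {
    geom$x_min + (CT - 0.24 * TA) * (geom$x_max - geom$x_min)
  })
  x_grid[x_grid < 0] <- 0                            # rows TA, cols CT
  stable_geom <- x_grid > 0 & A_ta > 0 &
    outer(d_ta, rep(1, grid_n)) < x_grid

  RM <- p_trace / geom$p_max
  TA_out <- rep(NA_real_, nt); CT_out <- rep(NA_real_, nt)
  feasible <- rep(FALSE, nt)
  prev <- init
  for (t in seq_len(nt)) {
    ft <- f_trace[t]
    if (is.na(ft)) next
    u_ta <- sqrt(2 * p_trace[t] * 1e3 / RHO_AIR) * u_factor   # m/s, by TA
    f_grid <- (u_ta / x_grid)                                  # kHz (m/s / mm)
    ok <- stable_geom & abs(f_grid - ft) <= tol_kHz & u_ta > 0
    if (!any(ok)) next
    idx <- which(ok, arr.ind = TRUE)
    ta_c <- ax[idx[, 1]]; ct_c <- ax[idx[, 2]]
    if (is.null(prev)) {
      pick <- which.min(ta_c^2 + ct_c^2)
    } else {
      pick <- which.min(ta_step_weight * (ta_c - prev[1])^2 +
                          (ct_c - prev[2])^2)
    }
    TA_out[t] <- ta_c[pick]; CT_out[t] <- ct_c[pick]
    feasible[t] <- TRUE
    prev <- c(TA_out[t], CT_out[t])
  }

  target <- !is.na(f_trace)
  missing_target <- which(target & !feasible)
  if (length(missing_target) > 0) {
    runs <- split(missing_target, cumsum(c(1, diff(missing_target) != 1)))
    too_long <- vapply(runs, length, integer(1)) > max_gap
    if (any(too_long)) {
      stop(sprintf("%d consecutive samples infeasible (max_gap = %d)",
                   max(vapply(runs, length, integer(1))), max_gap), call. = FALSE)
    }
    good <- which(feasible)
    if (length(good) >= 2) {
      TA_out[missing_target] <- approx(good, TA_out[good], xout = missing_target,
                                       rule = 2)$y
      CT_out[missing_target] <- approx(good, CT_out[good], xout = missing_target,
                                       rule = 2)$y
    } else if (length(good) == 1) {
      TA_out[missing_target] <- TA_out[good]
      CT_out[missing_target] <- CT_out[good]
    } else {
      stop("no feasible sample in the whole trace", call. = FALSE)
    }
  }

  # silent samples (no target frequency): hold the neighbouring posture
  if (any(!target) && any(target)) {
    good <- which(!is.na(TA_out))
    TA_out <- approx(good, TA_out[good], xout = seq_len(nt), rule = 2)$y
    CT_out <- approx(good, CT_out[good], xout = seq_len(nt), rule = 2)$y
  }

  act <- data.frame(time_s = times, RM = RM, CT = CT_out, TA = TA_out,
                    PCA_IA = TA_out, feasible = feasible | !target)
  states <- forward_map_df(RM, CT_out, TA_out, geom = geom)
  viol <- smoothness_violations(act, smooth_bound)
  structure(
    list(activations = act, states = states, f_kHz = states$f_1,
         target_f_kHz = f_trace, smoothness_violations = viol,
         tol_kHz = tol_kHz, geom = geom),
    class = "gesture_trajectory"
  )
}

# Sample indices whose activation step exceeds `bound` per 10 ms.
smoothness_violations <- function(act, bound = 0.1) {
  if (nrow(act) < 2) return(integer(0))
  dt <- diff(act$time_s)
  steps <- pmax(abs(diff(act$RM)), abs(diff(act$CT)), abs(diff(act$TA)))
  allowed <- bound * dt / 0.010
  which(steps > allowed & is.finite(steps)) + 1L
}

#' @export
print.gesture_trajectory <- function(x, ...) {
  nt <- nrow(x$activations)
  nf <- sum(!x$activations$feasible)
  cat(sprintf("Gesture trajectory: %d samples (%.1f ms), %d infeasible, %d smoothness violations\n",
              nt, 1e3 * diff(range(x$activations$time_s)), nf,
              length(x$smoothness_violations)))
  invisible(x)
}

#' Simulate the whistle produced by a motor gesture
#'
#' Runs the forward motor map along a gesture and synthesises the emitted
#' sound: at each sample the set of stable mode frequencies
#' `{n f_1 : n stable}` is computed, and the audio renders the dominant
#' (lowest stable) mode as a unit-amplitude phase-continuous tone, silent
#' where the whistle is unstable.
#'
#' @param gesture A `gesture_trajectory` from [invert_gesture()], or a data
#'   frame with columns `time_s`, `RM`, `CT`, `TA` (and optionally `PCA_IA`).
#' @param geom A [laryngeal_geometry()].
#' @param fs Audio sampling rate, Hz. Default 240000.
#' @param max_modes Highest mode to report. Default 5.
#' @return A list with `states` (per-sample data frame), `mode_freqs_kHz`
#'   (matrix sample x mode, NA where unstable), `audio` (numeric vector) and
#'   `fs`, plus `mode_jumps` (sample indices where the dominant mode changes).
#' @export
simulate_call <- function(gesture, geom = default_rat_geometry(), fs = 240e3,
                          max_modes = 5L) {
  act <- if (inherits(gesture, "gesture_trajectory")) gesture$activations else gesture
  stopifnot(is.data.frame(act), all(c("time_s", "RM", "CT", "TA") %in% names(act)))
  PCA_IA <- if ("PCA_IA" %in% names(act)) act$PCA_IA else act$TA
  st <- forward_map_df(act$RM, act$CT, act$TA, PCA_IA, geom = geom)
  nt <- nrow(st)
  n_stable_max <- ifelse(st$stable, pmax(0, ceiling(st$x / st$d) - 1), 0)
  mode_freqs <- sapply(seq_len(max_modes), function(n) {
    ifelse(st$stable & n <= n_stable_max, n * st$f_1, NA_real_)
  })
  if (nt == 1) mode_freqs <- matrix(mode_freqs, nrow = 1)
  colnames(mode_freqs) <- paste0("mode", seq_len(max_modes))

  # dominant (lowest stable) mode; constant-rate gestures may gate on/off
  f_dom_kHz <- ifelse(st$stable, st$f_1, NA_real_)
  t_audio <- seq(act$time_s[1], act$time_s[nt], by = 1 / fs)
  if (nt == 1) {
    f_inst <- rep(ifelse(is.na(f_dom_kHz), 0, f_dom_kHz) * 1e3, length(t_audio))
    gate <- rep(as.numeric(st$stable), length(t_audio))
  } else {
    f_inst <- approx(act$time_s, ifelse(is.na(f_dom_kHz), 0, f_dom_kHz),
                     xout = t_audio, rule = 2)$y * 1e3
    gate <- approx(act$time_s, as.numeric(st$stable), xout = t_audio,
                   method = "constant", rule = 2)$y
  }
  phase <- 2 * pi * cumsum(f_inst) / fs
  audio <- sin(phase) * gate
  dom_mode <- ifelse(st$stable, 1L, NA_integer_)
  jumps <- which(diff(is.na(dom_mode)) != 0) + 1L
  list(states = cbind(time_s = act$time_s, st), mode_freqs_kHz = mode_freqs,
       audio = audio, fs = fs, mode_jumps = jumps)
}

#' Frequency consequences of scaling the laryngeal geometry
#'
#' Re-runs the forward map along a fixed motor gesture with the impingement
#' length range (`x_min`, `x_max`) scaled jointly by each factor in
#' `length_scales`, leaving all activations unchanged. Under the
#' wall-impingement law a fixed stable state's frequency scales exactly as
#' `1/s`, so small anatomical changes shift whole call contours.
#'
#' @param gesture As in [simulate_call()].
#' @param geom A [laryngeal_geometry()].
#' @param length_scales Numeric vector of scale factors (> 0).
#' @return A data frame with columns `time_s`, `scale`, `f_1_kHz`, `stable`.
#' @export
geometry_perturbation <- function(gesture, geom = default_rat_geometry(),
                                  length_scales = c(0.8, 0.9, 1.0, 1.1, 1.2)) {
  stopifnot(all(length_scales > 0))
  act <- if (inherits(gesture, "gesture_trajectory")) gesture$activations else gesture
  PCA_IA <- if ("PCA_IA" %in% names(act)) act$PCA_IA else act$TA
  out <- lapply(length_scales, function(s) {
    g2 <- geom
    g2$x_min <- geom$x_min * s
    g2$x_max <- geom$x_max * s
    st <- forward_map_df(act$RM, act$CT, act$TA, PCA_IA, geom = g2)
    data.frame(time_s = act$time_s, scale = s, f_1_kHz = st$f_1,
               stable = st$stable)
  })
  do.call(rbind, out)
}
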