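#' Empirical constants of the shallow cavity-tone model
#'
#' The cavity-tone frequency law `f_n = u * (n - gamma) * kappa / x` carries
#' two empirical constants: `gamma`, the phase lag of the shear-layer
#' feedback, and `kappa`, the ratio of disturbance convection speed to
#' free-stream speed.
#'
#' @param gamma Dimensionless phase constant, in (0, 1). Default 0.25.
#' @param kappa Dimensionless speed ratio, positive. Default 1/1.75.
#' @return A list of class `cavity_constants`.
#' @export
#' @examples
#' cavity_constants()
cavity_constants <- function(gamma = 0.25, kappa = 1 / 1.75) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0, gamma < 1,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  structure(list(gamma = gamma, kappa = kappa), class = "cavity_constants")
}

WHISTLE_MODELS <- c("wall", "alar_edge", "cavity")

check_model <- function(model) {
  model <- match.arg(model, WHISTLE_MODELS)
  model
}

check_mode <- function(n) {
  if (!is.numeric(n) || any(n < 1) || any(n != round(n))) {
    stop("mode index `n` must be a positive integer", call. = FALSE)
  }
  as.integer(n)
}

#' Whistle frequency predicted by an aeroacoustic model
#'
#' Forward frequency laws of the three candidate intralaryngeal whistle
#' mechanisms. For a jet of exit speed `u` and impingement/cavity length `x`,
#' mode `n` sounds at
#' \deqn{f_n = n u / x \quad \mathrm{(wall)}, \qquad
#'       f_n = n u / (2x) \quad \mathrm{(alar\ edge)}, \qquad
#'       f_n = u (n - \gamma)\kappa / x \quad \mathrm{(cavity)}.}
#' Modes are possible stable whistle frequencies, not harmonics of an
#' oscillator: higher modes can sound without the first mode present.
#'
#' @param model One of `"wall"`, `"alar_edge"`, `"cavity"`.
#' @param u Jet exit speed, m/s (vectorised; `u >= 0`).
#' @param x Jet or cavity length, mm (vectorised; `x > 0`).
#' @param n Mode index, positive integer. Default 1.
#' @param constants [cavity_constants()] (used by the cavity model only).
#' @return Frequency in Hz.
#' @seealso [predicted_length()] for the algebraic inverse.
#' @export
#' @examples
#' whistle_frequency("wall", u = 33.2, x = 0.71)      # ~46.8 kHz
#' whistle_frequency("alar_edge", u = 33.2, x = 0.71) # exactly half
whistle_frequency <- function(model, u, x, n = 1L, constants = cavity_constants()) {
  model <- check_model(model)
  n <- check_mode(n)
  stopifnot(is.numeric(u), is.numeric(x))
  if (any(u < 0)) stop("jet speed `u` must be nonnegative", call. = FALSE)
  if (any(x <= 0)) stop("length `x` must be positive", call. = FALSE)
  x_m <- x * 1e-3
  switch(model,
    wall      = n * u / x_m,
    alar_edge = n * u / (2 * x_m),
    cavity    = u * (n - constants$gamma) * constants$kappa / x_m
  )
}

#' Jet or cavity length predicted from speed and frequency
#'
#' Each whistle model, rearranged, predicts the jet (or cavity) length that
#' would produce an observed frequency at a given jet speed:
#' `x = u/f` (wall, first mode), `x = u/(2f)` (alar edge),
#' `x = u (n - gamma) kappa / f` (cavity). This is the exact algebraic
#' inverse of [whistle_frequency()].
#'
#' @inheritParams whistle_frequency
#' @param f Observed frequency, Hz (positive).
#' @return Length in mm.
#' @export
#' @examples
#' predicted_length("wall", u = 33.2, f = 46760.56) # 0.71 mm
predicted_length <- function(model, u, f, n = 1L, constants = cavity_constants()) {
  model <- check_model(model)
  n <- check_mode(n)
  stopifnot(is.numeric(u), is.numeric(f))
  if (any(u <= 0)) stop("jet speed `u` must be positive", call. = FALSE)
  if (any(f <= 0)) stop("frequency `f` must be positive", call. = FALSE)
  x_m <- switch(model,
    wall      = n * u / f,
    alar_edge = n * u / (2 * f),
    cavity    = u * (n - constants$gamma) * constants$kappa / f
  )
  x_m * 1e3
}

#' Jet exit speed from tracheal flow and glottal area
#'
#' The mean convection speed of the coherent flow structures that set the
#' whistle frequency is approximated by the glottal jet exit speed,
#' `u = V / A_gl`.
#'
#' @param V Volumetric flow, ml/s (nonnegative, vectorised).
#' @param A_gl Glottal constriction area, mm^2 (positive).
#' @return Speed in m/s.
#' @export
#' @examples
#' jet_exit_speed(4, 0.1) # 40 m/s
jet_exit_speed <- function(V, A_gl) {
  stopifnot(is.numeric(V), is.numeric(A_gl))
  if (any(A_gl <= 0)) stop("glottal area `A_gl` must be positive", call. = FALSE)
  if (any(V < 0)) stop("flow `V` must be nonnegative", call. = FALSE)
  (V * 1e-6) / (A_gl * 1e-6)
}

#' Identify the whistle mode of a dominant spectral peak
#'
#' When a fictive USV shows several simultaneous modes, the dominant peak
#' `f_p` is assigned a mode number from the spacing to its closest neighbour:
#' adjacent modes are spaced by the first-mode frequency, so
#' `n = round(f_p / delta_f)` and `f_1 = f_p / n`.
#'
#' Ties in the rounding (half-integer ratios) break toward the lower mode,
#' since low modes dominate fictive USVs. A ratio farther than 0.25 from any
#' integer marks the estimate low-confidence (returned, not an error).
#'
#' @param f_p Dominant peak frequency, Hz (or any unit shared with
#'   `adjacent_mode_freqs`).
#' @param adjacent_mode_freqs Frequencies of other visible modes, same unit.
#' @return A list of class `mode_estimate` with fields `f_p`, `delta_f`, `n`,
#'   `f_1` and `low_confidence`.
#' @export
#' @examples
#' identify_mode(60e3, 40e3)          # n = 3, f_1 = 20 kHz
#' identify_mode(46.8e3, 70.2e3)      # n = 2, f_1 = 23.4 kHz
identify_mode <- function(f_p, adjacent_mode_freqs) {
  stopifnot(is.numeric(f_p), length(f_p) == 1L, f_p > 0,
            is.numeric(adjacent_mode_freqs), length(adjacent_mode_freqs) >= 1L,
            all(adjacent_mode_freqs > 0))
  closest <- adjacent_mode_freqs[which.min(abs(adjacent_mode_freqs - f_p))]
  delta_f <- abs(f_p - closest)
  if (delta_f == 0) {
    stop("degenerate spectrum: closest adjacent mode equals f_p", call. = FALSE)
  }
  ratio <- f_p / delta_f
  # nearest integer, ties toward the lower mode
  n <- floor(ratio + 0.5)
  if (ratio - floor(ratio) == 0.5) n <- floor(ratio)
  n <- max(1L, as.integer(n))
  structure(
    list(
      f_p = f_p,
      delta_f = delta_f,
      n = n,
      f_1 = f_p / n,
      low_confidence = abs(ratio - round(ratio)) > 0.25
    ),
    class = "mode_estimate"
  )
}

#' @export
print.mode_estimate <- function(x, ...) {
  cat(sprintf(
    "Whistle mode estimate: n = %d, f_1 = %.3f kHz (f_p = %.3f kHz, delta_f = %.3f kHz)%s\n",
    x$n, x$f_1 / 1e3, x$f_p / 1e3, x$delta_f / 1e3,
    if (x$low_confidence) " [low confidence]" else ""
  ))
  invisible(x)
}

#' Predict jet lengths for a table of (speed, frequency) observations
#'
#' Applies [predicted_length()] row-wise to a table with columns
#' `u_m_per_s` and `f_kHz` (and optionally `n`, default 1), for one model or
#' all three.
#'
#' @param tab A data frame with columns `u_m_per_s`, `f_kHz`, optionally `n`.
#' @param model `"wall"`, `"alar_edge"`, `"cavity"` or `"all"`.
#' @param constants [cavity_constants()].
#' @return The input with one `x_<model>_mm` column per requested model.
#' @export
predict_length_table <- function(tab, model = "all", constants = cavity_constants()) {
  stopifnot(is.data.frame(tab), all(c("u_m_per_s", "f_kHz") %in% names(tab)))
  n <- if ("n" %in% names(tab)) check_mode(tab$n) else rep(1L, nrow(tab))
  if (length(n) == 1L) n <- rep(n, nrow(tab))
  models <- if (identical(model, "all")) WHISTLE_MODELS else check_model(model)
  for (m in models) {
    tab[[paste0("x_", m, "_mm")]] <- vapply(seq_len(nrow(tab)), function(i) {
      predicted_length(m, tab$u_m_per_s[i], tab$f_kHz[i] * 1e3,
                       n = n[i], constants = constants)
    }, numeric(1))
  }
  tab
}
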