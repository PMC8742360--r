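#' Subglottal pressure from respiratory-muscle activation
#'
#' Subglottal pressure rises linearly with respiratory-muscle (RM)
#' activation, from 0 at rest to `p_max` (default 5 kPa) at full activation.
#'
#' @param RM Respiratory-muscle activation in \[0, 1\] (vectorised).
#' @param p_max Pressure at full activation, kPa.
#' @return Pressure in kPa.
#' @export
pressure_from_rm <- function(RM, p_max = 5) {
  check_activation(RM, "RM")
  RM * p_max
}

check_activation <- function(a, name) {
  if (!is.numeric(a) || any(!is.finite(a)) || any(a < 0) || any(a > 1)) {
    stop(sprintf("activation `%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(a)
}

#' Glottal area from laryngeal-muscle activations
#'
#' The glottal area is the sum of the membranous glottis (between the vocal
#' folds, closed by the thyroarytenoid, TA) and the cartilaginous glottis
#' (between the arytenoids, closed by the posterior cricoarytenoid +
#' interarytenoid combination, PCA.IA):
#' \deqn{A_{gl} = (1 - TA) A_{mmax} + (1 - PCA.IA) A_{cmax}.}
#'
#' @param TA Thyroarytenoid activation in \[0, 1\] (vectorised).
#' @param PCA_IA Combined posterior cricoarytenoid / interarytenoid
#'   activation in \[0, 1\].
#' @param geom A [laryngeal_geometry()].
#' @return Area in mm^2.
#' @export
glottal_area <- function(TA, PCA_IA, geom) {
  check_activation(TA, "TA")
  check_activation(PCA_IA, "PCA_IA")
  (1 - TA) * geom$A_mmax + (1 - PCA_IA) * geom$A_cmax
}

#' Jet impingement length from cricothyroid and thyroarytenoid activation
#'
#' Cricothyroid (CT) contraction rotates the thyroid wall away from the
#' glottis, lengthening the jet; the thyroarytenoid (TA) weakly counteracts
#' this rotation by shortening the vocal folds:
#' \deqn{x = x_{min} + (CT - 0.24\, TA)(x_{max} - x_{min}),}
#' floored at zero. The constant 0.24 calibrates the length to zero at full
#' TA and zero CT activation with the default geometry. A zero length marks
#' the whistle non-producible at that state (sound gated off), not an error.
#'
#' @param CT,TA Activations in \[0, 1\] (vectorised).
#' @param geom A [laryngeal_geometry()].
#' @param ta_counteraction Strength of the TA counter-rotation. Default 0.24.
#' @return Length in mm (possibly 0).
#' @export
impingement_length <- function(CT, TA, geom, ta_counteraction = 0.24) {
  check_activation(CT, "CT")
  check_activation(TA, "TA")
  x <- geom$x_min + (CT - ta_counteraction * TA) * (geom$x_max - geom$x_min)
  pmax(x, 0)
}

#' Tracheal flow through the glottal constriction (orifice law)
#'
#' The glottal constriction is modelled as a tube with an obstruction: an
#' incompressible orifice-plate law with area-ratio correction,
#' \deqn{V = C_d A_{gl} \sqrt{2 p_t / \rho} \Big/
#'       \sqrt{1 - (A_{gl}/A_{trachea})^2},}
#' with air density 1.184 kg/m^3 (25 degrees C). Flow is monotone increasing
#' in both pressure and area over the physiological range.
#'
#' @param p_t Subglottal pressure, kPa (nonnegative, vectorised).
#' @param A_gl Glottal area, mm^2 (`0 <= A_gl < A_trachea`; zero area gives
#'   zero flow).
#' @param geom A [laryngeal_geometry()].
#' @param Cd Discharge coefficient; defaults to the geometry's.
#' @return Flow in ml/s.
#' @export
#' @examples
#' orifice_flow(1, 0.1, default_rat_geometry()) # ~4.11 ml/s
orifice_flow <- function(p_t, A_gl, geom, Cd = geom$Cd) {
  stopifnot(is.numeric(p_t), is.numeric(A_gl))
  if (any(p_t < 0)) stop("pressure `p_t` must be nonnegative", call. = FALSE)
  if (any(A_gl < 0)) stop("glottal area must be nonnegative", call. = FALSE)
  if (any(A_gl >= geom$A_trachea)) {
    stop("glottal area must be smaller than the tracheal cross-section", call. = FALSE)
  }
  A_m2 <- A_gl * 1e-6
  beta2 <- (A_gl / geom$A_trachea)^2
  V_m3s <- Cd * A_m2 * sqrt(2 * p_t * 1e3 / RHO_AIR) / sqrt(1 - beta2)
  V_m3s * 1e6
}

#' Equivalent circular jet diameter of the glottal constriction
#'
#' The whistle stability criterion needs a jet diameter `d`; the glottal
#' constriction is not circular, so the equal-area circular diameter
#' `d = 2 sqrt(A_gl / pi)` is used.
#'
#' @param A_gl Glottal area, mm^2 (nonnegative, vectorised).
#' @return Diameter in mm.
#' @export
jet_diameter <- function(A_gl) {
  stopifnot(is.numeric(A_gl))
  if (any(A_gl < 0)) stop("glottal area must be nonnegative", call. = FALSE)
  2 * sqrt(A_gl / pi)
}

#' Stable whistle modes under the Strouhal stability criterion
#'
#' A mode `n` whistles stably when its Strouhal number `St_n = n f_1 d / u =
#' n d / x` satisfies `d/x <= St_n < 1`; equivalently `1 <= n < x/d`. When
#' the jet diameter reaches the impingement length (`d >= x`) no mode is
#' stable.
#'
#' @param d Jet diameter, mm.
#' @param x Impingement length, mm.
#' @return Integer vector of stable mode numbers (possibly empty).
#' @export
stable_modes <- function(d, x) {
  stopifnot(length(d) == 1L, length(x) == 1L)
  if (!is.finite(d) || !is.finite(x) || x <= 0 || d <= 0 || d >= x) {
    return(integer(0))
  }
  n_max <- ceiling(x / d) - 1L
  if (x / d == floor(x / d)) n_max <- as.integer(x / d) - 1L
  seq_len(max(0L, n_max))
}

#' Forward motor map: muscle activations to whistle state
#'
#' Chains the embodied model: RM sets subglottal pressure, TA and PCA.IA set
#' glottal area, the orifice law gives tracheal flow, flow over area gives
#' jet speed, CT and TA set impingement length, and the wall-impingement law
#' gives the first-mode frequency `f_1 = u / x`. The Strouhal stability
#' criterion then decides which modes (if any) can sound.
#'
#' @param RM,CT,TA Muscle activations in \[0, 1\] (scalars).
#' @param PCA_IA Posterior cricoarytenoid / interarytenoid activation;
#'   `NULL` (default) couples it to `TA`.
#' @param geom A [laryngeal_geometry()].
#' @return A list of class `motor_state` with fields `p_t` (kPa), `A_gl`
#'   (mm^2), `V` (ml/s), `u` (m/s), `x` (mm), `d` (mm), `f_1` (kHz; `NA`
#'   when unstable or silent), `St_1`, `stable_modes` (integer vector),
#'   `stable` and `silent` flags.
#' @export
#' @examples
#' forward_map(RM = 0.5, CT = 0.4, TA = 0.6)
forward_map <- function(RM, CT, TA, PCA_IA = NULL, geom = default_rat_geometry()) {
  if (is.null(PCA_IA)) PCA_IA <- TA
  check_activation(RM, "RM"); check_activation(CT, "CT")
  check_activation(TA, "TA"); check_activation(PCA_IA, "PCA_IA")
  p_t <- pressure_from_rm(RM, geom$p_max)
  A_gl <- glottal_area(TA, PCA_IA, geom)
  silent <- A_gl <= 0
  V <- if (silent) 0 else orifice_flow(p_t, A_gl, geom)
  u <- if (silent) 0 else jet_exit_speed(V, A_gl)
  x <- impingement_length(CT, TA, geom)
  d <- jet_diameter(A_gl)
  modes <- if (silent || u <= 0 || x <= 0) integer(0) else stable_modes(d, x)
  St_1 <- if (x > 0) d / x else Inf
  f_1 <- if (length(modes) > 0 && x > 0) u / x else NA_real_  # m/s per mm = kHz
  structure(
    list(
      RM = RM, CT = CT, TA = TA, PCA_IA = PCA_IA,
      p_t = p_t, A_gl = A_gl, V = V, u = u, x = x, d = d,
      f_1 = f_1, St_1 = St_1, stable_modes = modes,
      stable = length(modes) > 0, silent = silent
    ),
    class = "motor_state"
  )
}

#' @export
print.motor_state <- function(x, ...) {
  cat(sprintf(
    "Motor state: p_t %.2f kPa, A_gl %.3f mm^2, V %.2f ml/s, u %.1f m/s, x %.2f mm\n",
    x$p_t, x$A_gl, x$V, x$u, x$x))
  if (x$silent) {
    cat("  silent (glottis fully adducted)\n")
  } else if (!x$stable) {
    cat(sprintf("  unstable whistle (St_1 = %.2f)\n", x$St_1))
  } else {
    cat(sprintf("  f_1 = %.1f kHz, St_1 = %.2f, stable modes {%s}\n",
                x$f_1, x$St_1, paste(x$stable_modes, collapse = ", ")))
  }
  invisible(x)
}

#' Vectorised forward motor map
#'
#' [forward_map()] over parallel activation vectors (recycled to a common
#' length), one row per sample: the workhorse behind gesture simulation and
#' the inversion grid. PCA.IA defaults to TA (coupled adduction).
#'
#' @param RM,CT,TA Activation vectors in \[0, 1\].
#' @param PCA_IA Optional separate adduction vector; `NULL` couples to `TA`.
#' @param geom A [laryngeal_geometry()].
#' @return A data frame with columns `RM`, `CT`, `TA`, `PCA_IA`, `p_t`
#'   (kPa), `A_gl` (mm^2), `V` (ml/s), `u` (m/s), `x` (mm), `d` (mm),
#'   `St_1`, `stable`, `f_1` (kHz, `NA` where unstable).
#' @export
#' @examples
#' forward_map_df(RM = c(0.2, 0.4), CT = 0.5, TA = 0.6)
forward_map_df <- function(RM, CT, TA, PCA_IA = NULL, geom = default_rat_geometry()) {
  if (is.null(PCA_IA)) PCA_IA <- TA
  nlen <- max(length(RM), length(CT), length(TA))
  RM <- rep_len(RM, nlen); CT <- rep_len(CT, nlen)
  TA <- rep_len(TA, nlen); PCA_IA <- rep_len(PCA_IA, nlen)
  check_activation(RM, "RM"); check_activation(CT, "CT")
  check_activation(TA, "TA"); check_activation(PCA_IA, "PCA_IA")
  p_t <- pressure_from_rm(RM, geom$p_max)
  A_gl <- glottal_area(TA, PCA_IA, geom)
  V <- ifelse(A_gl > 0, orifice_flow(p_t, pmin(A_gl, geom$A_trachea * 0.999), geom), 0)
  u <- ifelse(A_gl > 0, V / A_gl, 0)
  x <- impingement_length(CT, TA, geom)
  d <- jet_diameter(A_gl)
  St_1 <- ifelse(x > 0, d / x, Inf)
  stable <- A_gl > 0 & u > 0 & x > 0 & d < x
  f_1 <- ifelse(stable, u / x, NA_real_)
  data.frame(RM = RM, CT = CT, TA = TA, PCA_IA = PCA_IA,
             p_t = p_t, A_gl = A_gl, V = V, u = u, x = x, d = d,
             St_1 = St_1, stable = stable, f_1 = f_1)
}
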