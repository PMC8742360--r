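#' Laryngeal geometry for the motor-control model
#'
#' Bundles the measured anatomical dimensions that parameterise the embodied
#' motor-control model: maximal glottal areas of the membranous and
#' cartilaginous glottis, the range of jet impingement lengths reachable by
#' cricothyroid rotation, the tracheal cross-section, and physiological caps.
#'
#' `x_min` and `x_max` are defined as 50% of the minimum and 150% of the
#' maximum predicted impingement length; with the rat defaults the
#' calibration constant 0.24 of [impingement_length()] places the length at
#' zero under full thyroarytenoid and zero cricothyroid activation.
#'
#' @param A_mmax Maximal membranous glottal area, mm^2.
#' @param A_cmax Maximal cartilaginous glottal area, mm^2.
#' @param x_min,x_max Minimal / maximal impingement length, mm.
#' @param A_trachea Tracheal cross-section area, mm^2.
#' @param x_wall_anat,x_alar_anat,x_cav_anat Measured anatomical lengths,
#'   mm (used for model-vs-anatomy comparison only).
#' @param p_max Subglottal pressure at full respiratory-muscle activation, kPa.
#' @param p_invivo_cap In vivo subglottal pressure ceiling, kPa.
#' @param V_cap In vivo flow ceiling, ml/s.
#' @param Cd Orifice discharge coefficient (dimensionless).
#' @return A list of class `laryngeal_geometry`.
#' @seealso [default_rat_geometry()]
#' @export
laryngeal_geometry <- function(A_mmax, A_cmax, x_min, x_max, A_trachea,
                               x_wall_anat = NA_real_, x_alar_anat = NA_real_,
                               x_cav_anat = NA_real_,
                               p_max = 5, p_invivo_cap = 3, V_cap = 10,
                               Cd = 1) {
  stopifnot(A_mmax > 0, A_cmax > 0, x_min > 0, x_max > x_min,
            A_trachea > 0, p_max > 0, p_invivo_cap <= p_max,
            V_cap > 0, Cd > 0)
  structure(
    list(
      A_mmax = A_mmax, A_cmax = A_cmax,
      x_min = x_min, x_max = x_max,
      A_trachea = A_trachea,
      x_wall_anat = x_wall_anat, x_alar_anat = x_alar_anat,
      x_cav_anat = x_cav_anat,
      p_max = p_max, p_invivo_cap = p_invivo_cap, V_cap = V_cap,
      Cd = Cd
    ),
    class = "laryngeal_geometry"
  )
}

#' Default rat laryngeal geometry
#'
#' A reference rat geometry reconstructed from published summary
#' measurements: anatomical wall/alar/cavity lengths 0.72/0.72/0.65 mm,
#' impingement-length range 0.35--1.81 mm (50% of the minimum and 150% of
#' the maximum predicted wall-jet length), cartilaginous glottal area
#' 0.075 mm^2 (chosen so orifice flow at phonation pressures 0.8--1.5 kPa
#' lies in the observed 2.6--3.7 ml/s band), membranous area 0.4 mm^2
#' (full-abduction flow consistent with quiet respiration), and tracheal
#' area 0.95 mm^2 (1.1 mm inner-diameter cannula).
#'
#' @return A [laryngeal_geometry()].
#' @export
#' @examples
#' default_rat_geometry()
default_rat_geometry <- function() {
  laryngeal_geometry(
    A_mmax = 0.4, A_cmax = 0.075,
    x_min = 0.35, x_max = 1.81,
    A_trachea = 0.95,
    x_wall_anat = 0.72, x_alar_anat = 0.72, x_cav_anat = 0.65
  )
}

#' @export
print.laryngeal_geometry <- function(x, ...) {
  cat("Laryngeal geometry:\n")
  cat(sprintf("  glottal areas      A_mmax %.3f mm^2, A_cmax %.3f mm^2, A_trachea %.3f mm^2\n",
              x$A_mmax, x$A_cmax, x$A_trachea))
  cat(sprintf("  impingement length x_min %.2f mm, x_max %.2f mm\n", x$x_min, x$x_max))
  cat(sprintf("  pressure/flow caps p_max %.1f kPa, in vivo %.1f kPa, V_cap %.1f ml/s, Cd %.2f\n",
              x$p_max, x$p_invivo_cap, x$V_cap, x$Cd))
  invisible(x)
}

#' Read / write a laryngeal geometry as YAML
#'
#' @param geom A [laryngeal_geometry()].
#' @param path File path.
#' @return `read_geometry()` returns a [laryngeal_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "laryngeal_geometry"))
  yaml::write_yaml(unclass(geom), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  do.call(laryngeal_geometry, vals)
}
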