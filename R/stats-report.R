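#' Summary statistics of one measurement group
#'
#' Group summaries of the form "mean +/- SD, n", as printed in measurement
#' tables, sufficient for pooled two-sample t tests.
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @param label Group name.
#' @param units Measurement units.
#' @return A list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n, label = "", units = "") {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2, n == round(n))
  structure(list(mean = mean, sd = sd, n = as.integer(n),
                 label = label, units = units),
            class = "summary_stats")
}

#' Pooled two-sample t test from summary statistics
#'
#' Two-sided two-sample Student t test for a difference between means,
#' computed from group summaries alone with the pooled (equal-variance)
#' standard deviation:
#' \deqn{s_p^2 = \frac{(n_a - 1) s_a^2 + (n_b - 1) s_b^2}{n_a + n_b - 2},
#'       \qquad t = \frac{\bar a - \bar b}{s_p \sqrt{1/n_a + 1/n_b}},}
#' with `n_a + n_b - 2` degrees of freedom. A Welch (unequal-variance)
#' variant is available via `welch = TRUE`.
#'
#' @param a,b [summary_stats()] of the two groups.
#' @param welch Use the Welch-Satterthwaite correction instead of pooling.
#' @return A list with `t`, `df`, `p` (two-sided) and `method`.
#' @export
#' @examples
#' a <- summary_stats(0.92, 0.21, 5)
#' b <- summary_stats(0.72, 0.10, 5)
#' pooled_t_from_summary(a, b)$p # ~0.09
pooled_t_from_summary <- function(a, b, welch = FALSE) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  if (a$n < 2 || b$n < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (welch) {
    se2a <- a$sd^2 / a$n
    se2b <- b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
    method <- "welch"
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    method <- "pooled"
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df), method = method)
}

#' Difference of group means
#'
#' @param a,b [summary_stats()] with matching units.
#' @return `b$mean - a$mean` (report rows state the orientation).
#' @export
mean_difference <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  if (!identical(a$units, b$units)) {
    stop(sprintf("unit mismatch: '%s' vs '%s'", a$units, b$units), call. = FALSE)
  }
  b$mean - a$mean
}

#' Frequency-to-flow slope of detected fUSV segments
#'
#' Ordinary least-squares slope of per-slice peak frequency against mean
#' flow, pooled over a recording's segments. Under the wall-impingement
#' model with fixed geometry, `f = V / (A_gl x)` is linear in flow, so the
#' slope estimates `1 / (A_gl x)` in kHz per (ml/s).
#'
#' @param segments Segments table with columns `f_p_kHz` and `flow_ml_s`
#'   (as returned by [detect_fusv_recording()]).
#' @return Slope in kHz per (ml/s).
#' @export
freq_flow_slope <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("f_p_kHz", "flow_ml_s") %in% names(segments)))
  if (nrow(segments) < 2 || length(unique(segments$flow_ml_s)) < 2) {
    stop("need at least two slices with distinct flow values", call. = FALSE)
  }
  unname(coef(lm(f_p_kHz ~ flow_ml_s, data = segments))["flow_ml_s"])
}

#' Model-vs-anatomy jet length comparison report
#'
#' Builds the comparison table between predicted and measured jet/cavity
#' lengths: one row per model with predicted and measured summaries, the
#' mean shortfall (measured minus predicted) and the pooled two-sample
#' t-test p value.
#'
#' @param predicted Named list of [summary_stats()], one per model.
#' @param measured Named list of [summary_stats()] of the anatomical
#'   lengths, same names.
#' @param digits_p Decimal places for the reported p value. Default 2.
#' @return A data frame with columns `model`, `predicted_mm`, `measured_mm`,
#'   `shortfall_mm`, `t`, `p`, `p_printed`.
#' @export
jet_length_report <- function(predicted, measured, digits_p = 2) {
  stopifnot(identical(sort(names(predicted)), sort(names(measured))))
  rows <- lapply(names(predicted), function(m) {
    tt <- pooled_t_from_summary(predicted[[m]], measured[[m]])
    data.frame(
      model = m,
      predicted_mm = predicted[[m]]$mean,
      measured_mm = measured[[m]]$mean,
      shortfall_mm = mean_difference(predicted[[m]], measured[[m]]),
      t = tt$t,
      p = tt$p,
      p_printed = round(tt$p, digits_p)
    )
  })
  do.call(rbind, rows)
}

#' Bundled reference summary statistics
#'
#' Published group summaries (mean, SD, n) from the excised-larynx
#' experiments: predicted vs measured jet/cavity lengths per whistle model,
#' peak frequencies before/after filling the ventral pouch in rats and mice,
#' and the frequency-to-flow slope before/after fixation. One row per
#' comparison; use [summary_row()] to turn a row into a pair of
#' [summary_stats()].
#'
#' @return A data frame with columns `comparison`, `units`, and
#'   `label_a`/`mean_a`/`sd_a`/`n_a` (likewise `_b`).
#' @export
reference_summaries <- function() {
  read.csv(system.file("extdata", "reference_summaries.csv",
                       package = "usvwhistle"))
}

#' @rdname reference_summaries
#' @param comparison A `comparison` value present in [reference_summaries()].
#' @export
summary_row <- function(comparison) {
  tab <- reference_summaries()
  row <- tab[tab$comparison == comparison, ]
  if (nrow(row) != 1) stop("unknown comparison: ", comparison, call. = FALSE)
  list(
    a = summary_stats(row$mean_a, row$sd_a, row$n_a, row$label_a, row$units),
    b = summary_stats(row$mean_b, row$sd_b, row$n_b, row$label_b, row$units)
  )
}
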