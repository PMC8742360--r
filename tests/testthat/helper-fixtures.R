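# Shared fixtures, all built in code.

# Geometry with a huge trachea: removes the area-ratio correction so
# closed-form orifice values can be checked directly.
open_trachea_geometry <- function() {
  laryngeal_geometry(
    A_mmax = 0.4, A_cmax = 0.075, x_min = 0.35, x_max = 1.81,
    A_trachea = 1e6, x_wall_anat = 0.72
  )
}

# One default synthetic ramp per session, reused across tests (generation
# and detection both cost ~1 s at 240 kHz).
default_ramp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_ramp(ramp_spec(seed = 11L))
    cache
  }
})

default_detection <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- detect_fusv_recording(default_ramp()$recording)
    cache
  }
})

# Mean truth value of a per-sample series over a [t0, t1) window.
window_mean <- function(x, fs, t0, t1) {
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(length(x), ceiling(t1 * fs))
  mean(x[i0:i1])
}
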