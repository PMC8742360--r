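test_that("inversion recovers smooth gestures from frequency and pressure", {
  # forward-generate traces from smooth gestures at several adduction
  # levels, then invert anchored at the known starting posture
  for (TA_level in c(0.5, 0.6, 0.7)) {
    ge <- generate_smooth_gesture(TA_level = TA_level)
    st <- forward_map_df(ge$RM, ge$CT, ge$TA)
    expect_true(all(st$stable))
    inv <- invert_gesture(st$f_1, st$p_t, init = c(ge$TA[1], ge$CT[1]),
                          times = ge$time_s)
    expect_equal(inv$activations$RM, ge$RM)
    expect_lt(max(abs(inv$activations$TA - ge$TA)), 0.05)
    expect_lt(max(abs(inv$activations$CT - ge$CT)), 0.05)
    # the recovered gesture reproduces the target frequencies
    expect_lt(max(abs(inv$f_kHz - st$f_1), na.rm = TRUE), inv$tol_kHz + 1e-9)
  }
})

test_that("constant targets give stationary recovered activations", {
  inv <- invert_gesture(rep(50, 40), rep(1.8, 40))
  expect_equal(sd(inv$activations$TA), 0)
  expect_equal(sd(inv$activations$CT), 0)
  expect_equal(sd(inv$activations$RM), 0)
  expect_length(inv$smoothness_violations, 0)
})

test_that("unattainable frequency traces are reported infeasible", {
  # far beyond any stable state of the geometry at low pressure
  expect_error(invert_gesture(rep(200, 10), rep(0.1, 10)), "infeasible")
  expect_error(invert_gesture(rep(50, 10), rep(10, 10)), "p_max")
})

test_that("call-type targets invert within tolerance", {
  for (ct in c("flat22", "step50", "trill50")) {
    tg <- generate_call_targets(ct)
    inv <- invert_gesture(tg$f_kHz, tg$p_kPa, times = tg$time_s)
    expect_true(all(inv$activations$feasible))
    expect_lt(max(abs(inv$f_kHz - tg$f_kHz), na.rm = TRUE), 0.5 + 1e-9)
  }
})

test_that("trill inversion oscillates CT at the modulation rate", {
  dur <- 0.5
  tg <- generate_call_targets("trill50", duration = dur)
  inv <- invert_gesture(tg$f_kHz, tg$p_kPa, times = tg$time_s)
  ct <- inv$activations$CT - mean(inv$activations$CT)
  spec <- Mod(stats::fft(ct))[2:(length(ct) %/% 2)]
  freqs <- seq_along(spec) / dur
  expect_equal(freqs[which.max(spec)], 60, tolerance = 0.05)
})

test_that("simulated calls rise with respiratory drive and gate on stability", {
  # monotonically rising RM at fixed larynx: frequency rises while stable
  n <- 50
  ge <- data.frame(time_s = (0:(n - 1)) * 1e-3,
                   RM = seq(0.1, 0.6, length.out = n),
                   CT = rep(0.5, n), TA = rep(0.6, n))
  sim <- simulate_call(ge, fs = 48e3)
  f <- sim$states$f_1[sim$states$stable]
  expect_true(all(diff(f) > 0))
  # square-root-of-pressure law through the jet speed
  expect_equal(f[length(f)] / f[1],
               sqrt(sim$states$p_t[n] / sim$states$p_t[1]),
               tolerance = 1e-6)

  # crossing d/x = 1 gates the audio off exactly at the crossing
  ge2 <- data.frame(time_s = (0:(n - 1)) * 1e-3,
                    RM = rep(0.4, n),
                    CT = seq(0.6, 0.05, length.out = n), TA = rep(0.3, n))
  sim2 <- simulate_call(ge2, fs = 48e3)
  st <- sim2$states
  expect_true(any(st$stable) && any(!st$stable))
  cross <- which(!st$stable)[1]
  expect_true(all(st$St_1[!st$stable] >= 1))
  silent_part <- sim2$audio[floor(st$time_s[cross] * sim2$fs + 2):length(sim2$audio)]
  expect_equal(max(abs(silent_part)), 0)

  # stable mode table lists integer multiples of f_1 at a state whose
  # narrow jet (high TA) leaves more than one mode below x/d
  ge3 <- data.frame(time_s = 0, RM = 0.4, CT = 0.5, TA = 0.8)
  sim3 <- simulate_call(ge3, fs = 48e3)
  expect_gte(sim3$states$x / sim3$states$d, 2)
  expect_equal(sim3$mode_freqs_kHz[1, "mode2"],
               2 * sim3$mode_freqs_kHz[1, "mode1"],
               ignore_attr = TRUE)
})

test_that("a flat 22 kHz gesture stays within tolerance when simulated", {
  tg <- generate_call_targets("flat22")
  inv <- invert_gesture(tg$f_kHz, tg$p_kPa, times = tg$time_s)
  sim <- simulate_call(inv, fs = 96e3)
  f <- sim$states$f_1[sim$states$stable]
  expect_true(all(abs(f - 22) < 0.5))
})

test_that("geometry scaling leaves gestures alone and rescales frequency", {
  ge <- generate_smooth_gesture()
  gp <- geometry_perturbation(ge, length_scales = c(0.8, 1.0, 1.2))
  base <- gp$f_1_kHz[gp$scale == 1.0]
  st <- forward_map_df(ge$RM, ge$CT, ge$TA)
  expect_equal(base, st$f_1) # scale 1 is the identity
  # where the whistle stays stable, f scales by exactly 1/s; shrinking can
  # push the jet diameter past the shortened length and gate samples off
  for (s in c(0.8, 1.2)) {
    fs_ <- gp$f_1_kHz[gp$scale == s]
    still <- gp$stable[gp$scale == s]
    expect_equal(fs_[still], base[still] / s, tolerance = 1e-12)
    if (any(!still)) {
      expect_true(all(st$d[!still] >= s * st$x[!still]))
    }
  }
})

test_that("a 20% longer impingement length shifts 60 kHz calls down 10 kHz", {
  # wall-model evaluation at 54 m/s: u/x at 0.90 vs 1.08 mm
  u <- 54
  f0 <- whistle_frequency("wall", u, 0.90) / 1e3
  f1 <- whistle_frequency("wall", u, 1.08) / 1e3
  expect_equal(f0, 60, tolerance = 1e-9)
  expect_equal(f0 - f1, 10, tolerance = 1e-9)
})

test_that("gesture smoothness flags steps above the bound", {
  act <- data.frame(time_s = c(0, 0.01, 0.02), RM = c(0.1, 0.1, 0.1),
                    CT = c(0.2, 0.35, 0.36), TA = c(0.5, 0.5, 0.5))
  expect_equal(usvwhistle:::smoothness_violations(act, 0.1), 2L)
  act$CT <- c(0.2, 0.25, 0.3)
  expect_length(usvwhistle:::smoothness_violations(act, 0.1), 0L)
})
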