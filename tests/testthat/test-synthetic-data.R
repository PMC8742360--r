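test_that("ramp generation is a deterministic function of the seed", {
  s <- ramp_spec(seed = 5L, p_peak = 1.2)
  r1 <- generate_ramp(s)
  r2 <- generate_ramp(s)
  expect_identical(r1$recording$sound, r2$recording$sound)
  expect_identical(r1$truth, r2$truth)
  r3 <- generate_ramp(ramp_spec(seed = 6L, p_peak = 1.2))
  expect_false(identical(r1$recording$sound, r3$recording$sound))
})

test_that("ramp pressure, flow and whistle activity follow the ramp_spec", {
  r <- default_ramp()
  spec <- ramp_spec(seed = 11L)
  rec <- r$recording
  tr <- r$truth
  # piecewise-linear up-down pressure reaching the peak
  expect_equal(max(rec$pressure), spec$p_peak, tolerance = 1e-3)
  expect_equal(rec$pressure[1], 0)
  # flow follows the orifice law through the cartilaginous glottis
  i <- round(length(rec$pressure) * 0.3)
  expect_equal(rec$flow[i],
               orifice_flow(rec$pressure[i], spec$geometry$A_cmax, spec$geometry))
  # whistle active exactly above the phonation threshold
  expect_true(all(rec$pressure[tr$active] >= spec$phonation_threshold))
  expect_true(all(rec$pressure[!tr$active] < spec$phonation_threshold))
  # in vitro flows at phonation lie in the observed 2.6-3.7 ml/s band
  expect_gte(min(rec$flow[tr$active]), 2.6)
  expect_lte(max(rec$flow[tr$active]), 3.7 + 0.15)
  # flow never exceeds the 10 ml/s in vivo ceiling
  expect_lt(max(rec$flow), spec$geometry$V_cap)
  # whistle frequencies stay inside the in vivo 18-96 kHz range
  expect_gte(min(tr$f1_kHz[tr$active]), 18)
  expect_lte(max(tr$f1_kHz[tr$active]), 96)
})

test_that("whistle-free ramps yield no detections at preset thresholds", {
  r0 <- generate_ramp(ramp_spec(whistle_amplitude = 0, seed = 21L))
  det <- detect_fusv_recording(r0$recording)
  expect_equal(nrow(det$segments), 0L)
  # turbulence noise reads as high entropy throughout
  expect_true(all(det$slice_entropy > 0.7))
})

test_that("the detector recovers injected whistles and their frequencies", {
  r <- default_ramp()
  det <- default_detection()
  segs <- det$segments
  expect_gt(nrow(segs), 0)

  # >= 90% of the injected whistle duration is recovered
  iv <- r$truth$intervals
  true_dur <- sum(iv$t_end_s - iv$t_start_s)
  covered <- 0
  for (k in seq_len(nrow(iv))) {
    o <- pmin(segs$t_end_s, iv$t_end_s[k]) - pmax(segs$t_start_s, iv$t_start_s[k])
    covered <- covered + sum(pmax(o, 0))
  }
  expect_gte(covered / true_dur, 0.9)

  # slice entropy separates tonal from noise regimes
  fs <- r$recording$fs
  slice_dur <- 6 * 2048 / fs
  slice_mid <- (seq_along(det$slice_entropy) - 0.5) * slice_dur
  tonal <- vapply(slice_mid, function(tm) {
    any(tm >= iv$t_start_s & tm <= iv$t_end_s)
  }, logical(1))
  expect_lt(median(det$slice_entropy[tonal]),
            median(det$slice_entropy[!tonal]))

  # ridge frequencies match the generator truth within 2 spectrogram bins
  # on slices fully inside a whistle interval
  bin_kHz <- fs / 2048 / 1e3
  inside <- vapply(seq_len(nrow(segs)), function(i) {
    any(segs$t_start_s[i] >= iv$t_start_s & segs$t_end_s[i] <= iv$t_end_s)
  }, logical(1))
  expect_gt(sum(inside), 0)
  f_true <- vapply(which(inside), function(i) {
    window_mean(r$truth$f1_kHz, fs, segs$t_start_s[i], segs$t_end_s[i])
  }, numeric(1))
  expect_true(all(abs(segs$f_p_kHz[inside] - f_true) <= 2 * bin_kHz))
})

test_that("thresholds derived from noise ramps sit above the tonal regime", {
  r0 <- generate_ramp(ramp_spec(whistle_amplitude = 0, seed = 22L))
  g <- usv_spectrogram(r0$recording)
  ent <- scaled_entropy(g)
  fl <- r0$recording$flow[g$starts + 1024]
  thr <- derive_threshold(ent[fl >= 0.95 * max(fl)])
  expect_gt(thr, 0.7) # conservative relative to the preset
  expect_lt(thr, 1)
})

test_that("multi-mode clips are labelled with the correct dominant mode", {
  clip <- generate_multimode_clip(f_1 = 23.4, modes = c(2, 3), dominant = 2,
                                  duration = 0.25, seed = 3L)
  g <- usv_spectrogram(clip$sound, fs = clip$fs)
  spec <- colMeans(g$power)
  # the two spectral peaks: dominant and its neighbour
  pk <- order(spec, decreasing = TRUE)
  f_peak <- g$freqs[pk[1]]
  others <- g$freqs[pk[2:8]]
  others <- others[abs(others - f_peak) > 5 * clip$fs / 2048][1]
  m <- identify_mode(f_peak, others)
  expect_equal(m$n, 2L)
  expect_equal(m$f_1 / 1e3, 23.4, tolerance = 0.01)

  # single mode and adjacent equal-amplitude pair
  clip1 <- generate_multimode_clip(20, modes = 1L, duration = 0.05, seed = 4L)
  expect_equal(clip1$truth$f_p_kHz, 20)
  clip12 <- generate_multimode_clip(20, modes = c(1, 2), duration = 0.05,
                                    side_amplitude = 1, seed = 4L)
  expect_equal(clip12$truth$modes, c(1L, 2L))

  expect_error(generate_multimode_clip(60, modes = c(1, 3), fs = 240e3),
               "alias")
})

test_that("generated ramps refuse sampling rates that alias the whistle", {
  g <- default_rat_geometry()
  expect_error(generate_ramp(ramp_spec(fs = 60e3, seed = 1L, geometry = g)),
               "mode frequencies")
})

test_that("call targets are feasible, bounded and empty when asked", {
  for (ct in c("flat22", "step50", "trill50")) {
    tg <- generate_call_targets(ct)
    expect_true(all(tg$p_kPa <= 3))
    expect_true(all(tg$p_kPa >= 0))
  }
  tg <- generate_call_targets("trill50")
  expect_equal(max(tg$f_kHz), 55, tolerance = 0.01)
  expect_equal(nrow(generate_call_targets("flat22", duration = 0)), 0L)
  # an impossible request errors at generation, naming samples
  small <- laryngeal_geometry(A_mmax = 0.4, A_cmax = 0.075, x_min = 0.05,
                              x_max = 0.1, A_trachea = 0.95)
  expect_error(generate_call_targets("flat22", geom = small), "infeasible")
})

test_that("ramp fixtures round-trip through WAV + CSV + YAML sidecars", {
  r <- generate_ramp(ramp_spec(seed = 9L, ramp_rate = 1.66, p_peak = 1.0,
                               fs = 48e3, geometry = {
                                 g <- default_rat_geometry()
                                 g$x_wall_anat <- 2.5 # keep modes below fs/2
                                 g
                               }))
  stem <- tempfile()
  write_ramp(r, stem)
  rec2 <- read_ramp(stem)
  expect_equal(rec2$fs, 48e3)
  expect_equal(rec2$sound, r$recording$sound, tolerance = 1e-6)
  expect_equal(rec2$pressure, r$recording$pressure)
  meta <- yaml::read_yaml(paste0(stem, ".yml"))
  expect_equal(meta$units$flow, "ml/s")
  file.remove(paste0(stem, c(".wav", "_aux.csv", ".yml")))
})
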