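test_that("conditioning preserves the passband and rejects low frequencies", {
  fs <- 240e3
  t <- seq(0, 0.2, by = 1 / fs)
  mk <- function(x) ramp_recording(x, rep(1, length(x)), rep(2, length(x)), fs)

  # 50 kHz sits mid-band: amplitude preserved within 1%
  tone50 <- sin(2 * pi * 50e3 * t)
  out <- condition_recording(mk(tone50))
  mid <- seq(round(0.05 * fs), round(0.15 * fs))
  expect_equal(sqrt(mean(out$sound[mid]^2)), sqrt(0.5), tolerance = 0.01)

  # 1 kHz is below the 2.5 kHz corner: a 3rd-order high-pass edge applied
  # forward-backward attenuates (2.5/1)^6-fold in power, i.e. >= 30 dB
  tone1 <- sin(2 * pi * 1e3 * t)
  out <- condition_recording(mk(tone1))
  atten_db <- 10 * log10(mean(tone1[mid]^2) / mean(out$sound[mid]^2))
  expect_gt(atten_db, 30)

  # zero in, zero out
  out <- condition_recording(mk(numeric(length(t))))
  expect_equal(max(abs(out$sound)), 0)
})

test_that("conditioning resamples all channels to the target rate", {
  fs_raw <- 120e3
  n <- fs_raw %/% 5
  rec <- ramp_recording(sin(2 * pi * 30e3 * (0:(n - 1)) / fs_raw),
                        seq(0, 1, length.out = n), rep(3, n), fs_raw)
  expect_warning(out <- condition_recording(rec), "band")
  expect_equal(out$fs, 240e3)
  expect_equal(length(out$sound), length(out$pressure))
  # pressure ramp shape survives resampling
  expect_equal(out$pressure[round(length(out$pressure) / 2)], 0.5,
               tolerance = 0.01)
})

test_that("recordings with mismatched channels are rejected", {
  expect_error(ramp_recording(1:10, 1:9, 1:10, 240e3), "length")
  expect_error(ramp_recording(numeric(0), numeric(0), numeric(0), 240e3),
               "nonempty")
})

test_that("spectrogram localises tones and returns zero for silence", {
  fs <- 240e3
  nfft <- 2048L
  f0 <- 50 * fs / nfft # an exact bin centre
  x <- sin(2 * pi * f0 * (0:(fs / 10)) / fs)
  g <- usv_spectrogram(x, fs = fs, nfft = nfft)
  expect_true(all(g$power >= 0))
  expect_equal(length(g$freqs), nfft / 2 + 1)
  peak_bins <- apply(g$power, 1, which.max)
  expect_true(all(g$freqs[peak_bins] == f0))

  g0 <- usv_spectrogram(numeric(fs / 10), fs = fs, nfft = nfft)
  expect_equal(max(g0$power), 0)

  expect_error(usv_spectrogram(x, fs = fs, nfft = 1000L), "power of two")
  expect_warning(usv_spectrogram(numeric(100), fs = fs, nfft = nfft),
                 "shorter")
})

test_that("white noise yields a flat expected spectrum", {
  fs <- 240e3
  set.seed(42)
  x <- rnorm(fs / 2)
  g <- usv_spectrogram(x, fs = fs, nfft = 2048L)
  inb <- which(g$freqs >= 15e3 & g$freqs <= 100e3)
  # sum the periodogram over time per frequency band; for white noise each
  # band total is chi-square distributed around a common mean
  bands <- split(inb, cut(seq_along(inb), 8, labels = FALSE))
  sums <- vapply(bands, function(ix) sum(g$power[, ix]), numeric(1))
  per_bin <- vapply(bands, function(ix) length(ix) * nrow(g$power), numeric(1))
  rate <- sums / per_bin
  z <- (rate - mean(rate)) / (mean(rate) / sqrt(per_bin))
  # 1% level with a Bonferroni margin over the 8 bands
  expect_true(all(abs(z) < qnorm(1 - 0.005 / 8)))
})

test_that("scaled entropy matches closed forms on canonical distributions", {
  fs <- 240e3
  nfft <- 2048L
  g <- usv_spectrogram(numeric(fs %/% 10), fs = fs, nfft = nfft)
  inb <- which(g$freqs >= 15e3 & g$freqs <= 100e3)
  denom <- log2(nfft / 2)

  # all in-band power in one bin -> 0
  g$power[, inb[10]] <- 1
  expect_equal(scaled_entropy(g), rep(0, nrow(g$power)))

  # uniform power over the in-band bins -> log2(N_band) / log2(nfft/2)
  g$power[] <- 0
  g$power[, inb] <- 1
  expect_equal(scaled_entropy(g), rep(log2(length(inb)) / denom, nrow(g$power)))

  # two equal bins -> 1 bit
  g$power[] <- 0
  g$power[, inb[c(3, 9)]] <- 2.5
  expect_equal(scaled_entropy(g), rep(1 / denom, nrow(g$power)))

  # all-zero bins read as maximally noise-like
  g$power[] <- 0
  expect_equal(scaled_entropy(g), rep(1, nrow(g$power)))

  # the alternative printed scaling is selectable
  g$power[] <- 0
  g$power[, inb[c(3, 9)]] <- 1
  expect_equal(scaled_entropy(g, denominator = "squared_half"),
               rep(1 / log2(nfft^2 / 2), nrow(g$power)))

  expect_error(scaled_entropy(g, band = c(130e3, 140e3)), "band")
})

test_that("slice aggregation is mass-conserving and drops partial tails", {
  x <- runif(30)
  s <- slice_means(x, 6L)
  expect_length(s, 5L)
  expect_equal(mean(s), mean(x)) # exact when length divides evenly
  # trailing partial slice is dropped
  expect_length(slice_means(c(x, 0.5), 6L), 5L)
  expect_length(slice_means(x[1:5], 6L), 0L)
})

test_that("threshold derivation is mean minus two SDs with presets", {
  samples <- c(rep(0.8, 5), rep(1.0, 5)) # mean 0.9, sd ~0.105
  expect_equal(derive_threshold(samples), mean(samples) - 2 * sd(samples))
  expect_equal(derive_threshold(rep(0.85, 12)), 0.85)
  expect_equal(derive_threshold(NULL, "rat"), 0.7)
  expect_equal(derive_threshold(NULL, "mouse"), 0.8)
  expect_error(derive_threshold(rep(0.9, 5)), "at least 10")
})

test_that("fUSV detection applies the two-slice minimum and one-slice bridge", {
  # a clean below-threshold run
  seg <- detect_fusv(c(0.9, 0.6, 0.6, 0.9), 0.7)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start_slice, seg$end_slice), c(2L, 3L))

  # a one-slice break does not split the call
  seg <- detect_fusv(c(0.6, 0.8, 0.6), 0.7)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start_slice, seg$end_slice), c(1L, 3L))

  # an isolated below-threshold slice is not a call
  expect_equal(nrow(detect_fusv(c(0.9, 0.6, 0.9, 0.9), 0.7)), 0L)

  # two-slice breaks do split
  seg <- detect_fusv(c(0.6, 0.6, 0.9, 0.9, 0.6, 0.6), 0.7)
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$end_slice >= seg$start_slice))

  expect_equal(nrow(detect_fusv(rep(0.9, 10), 0.7)), 0L)
})

test_that("ridge tracking follows chirps, noisy tones and the stronger tone", {
  fs <- 240e3
  nfft <- 2048L
  dur <- 0.3
  t <- (0:(dur * fs - 1)) / fs

  # noiseless linear chirp 30 -> 60 kHz: the ridge (a bin-quantised trace)
  # stays within one bin of the quantised instantaneous frequency
  f_inst <- 30e3 + (60e3 - 30e3) * t / dur
  x <- sin(2 * pi * cumsum(f_inst) / fs)
  g <- usv_spectrogram(x, fs = fs, nfft = nfft)
  ridge <- extract_ridge(g)
  truth <- 30e3 + (60e3 - 30e3) * g$times / dur
  bin <- fs / nfft
  expect_true(all(abs(ridge - round(truth / bin) * bin) <= bin))

  # constant tone in white noise at 20 dB SNR
  set.seed(7)
  tone <- sin(2 * pi * 40e3 * t)
  noise <- rnorm(length(t), sd = sqrt(0.5) / 10)
  g <- usv_spectrogram(tone + noise, fs = fs, nfft = nfft)
  ridge <- extract_ridge(g)
  expect_true(all(abs(ridge - 40e3) <= fs / nfft))

  # two tones: the ridge follows the one 20 dB stronger
  x2 <- sin(2 * pi * 70e3 * t) + 0.1 * sin(2 * pi * 30e3 * t)
  g <- usv_spectrogram(x2, fs = fs, nfft = nfft)
  ridge <- extract_ridge(g)
  expect_true(all(abs(ridge - 70e3) <= fs / nfft))

  g$power[] <- 0
  expect_error(extract_ridge(g), "all-zero")
})

test_that("segment features average channels over slice windows", {
  fs <- 240e3
  n <- fs %/% 5
  t <- (0:(n - 1)) / fs
  A <- 0.3
  rec <- ramp_recording(
    sound = A * sin(2 * pi * 40e3 * t),
    pressure = seq(0, 2, length.out = n), # linear ramp
    flow = rep(3, n),
    fs = fs
  )
  g <- usv_spectrogram(rec, nfft = 2048L)
  seg <- data.frame(segment_id = 1L, start_slice = 1L,
                    end_slice = length(g$times) %/% 6L, n_below = 1L)
  feats <- segment_features(rec, g, seg, slice_size = 6L)

  expect_equal(feats$flow_ml_s, rep(3, nrow(feats)))
  expect_equal(feats$rms_Pa, rep(A / sqrt(2), nrow(feats)), tolerance = 0.01)
  # ramp means equal the ramp value at slice centres
  centres <- (feats$t_start_s + feats$t_end_s) / 2
  expect_equal(feats$pressure_kPa, 2 * centres / (n / fs),
               tolerance = 2 * 2048 / n)
  expect_equal(feats$f_p_kHz, rep(40, nrow(feats)), tolerance = 0.01)
})
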