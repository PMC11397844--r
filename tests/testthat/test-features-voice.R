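test_that("f0 estimation: pulse train, pure tone, and unvoiced noise", {
  v <- synth_voice(120, 0.3, 0.2, 25, duration = 2, rate = 16000, seed = 1)
  expect_equal(estimate_f0(v$samples, v$rate), 120, tolerance = 1 / 120)

  t <- seq(0, 1, by = 1 / 16000)
  expect_equal(estimate_f0(sin(2 * pi * 200 * t), 16000), 200,
               tolerance = 1 / 200)

  set.seed(2)
  expect_true(is.na(estimate_f0(rnorm(16000), 16000)))
  expect_true(is.na(estimate_f0(rep(0, 16000), 16000)))
})

test_that("jitter and shimmer match hand arithmetic", {
  expect_equal(unname(jitter(rep(10, 50))), c(0, 0))
  alt <- rep(c(10.0, 10.2), 25)
  j <- jitter(alt)
  expect_equal(unname(j["ms"]), 0.2, tolerance = 1e-6)
  expect_equal(unname(j["pct"]), 100 * 0.2 / 10.1, tolerance = 1e-3)

  s <- shimmer(rep(c(1, 0.5), 20))
  expect_equal(unname(s["db"]), 20 * log10(2), tolerance = 1e-9)
  expect_equal(unname(s["pct"]), 100 * 0.5 / 0.75, tolerance = 1e-9)
})

test_that("HNR hits its limits: high for clean periodic, <= 0 for white noise", {
  clean <- synth_voice(120, 0, 0, Inf, duration = 2, rate = 16000, seed = 3)
  expect_gt(hnr(clean$samples, clean$rate, 120), 15)
  t <- seq(0, 1, by = 1 / 16000)
  pure <- sin(2 * pi * 120 * t)
  expect_gt(hnr(pure, 16000, 120), 30)
  set.seed(4)
  expect_lt(hnr(rnorm(16000), 16000, 120), 0)
})

test_that("spectral descriptors localize tones and count 38 per segment", {
  t <- seq(0, 0.5, by = 1 / 16000)
  f <- voice_spectral_features(sin(2 * pi * 100 * t), 16000)
  bands <- f[grep("^band\\.", names(f))]
  expect_gt(unname(f["band.80_120"]) / sum(bands), 0.95)
  set.seed(5)
  fn <- voice_spectral_features(rnorm(8000), 16000)
  expect_gt(unname(fn["spec.flatness"]), 0.7)
  d <- digibm:::segment_descriptors(sin(2 * pi * 100 * t) +
                                      0.01 * rnorm(length(t)), 16000)
  expect_length(d, 38)
  expect_equal(names(d), digibm:::voice_descriptor_names())
})

test_that("voice extraction yields 495 features; scaling invariances hold", {
  v <- synth_voice(120, 1, 0.5, 20, duration = 3, rate = 16000, seed = 6)
  f <- extract_voice(v, "phonation")
  expect_length(f, 495)
  expect_length(unique(names(f)), 495)
  expect_equal(sum(is.na(f)), 0)

  # amplitude scaling: f0, jitter %, shimmer, MFCC unchanged
  v_half <- audio_clip(v$samples * 0.5, v$rate)
  f_half <- extract_voice(v_half, "phonation")
  inv <- grep("\\.(f0|jitter_pct|shimmer_db|shimmer_pct|mfcc[0-9]+)\\.",
              names(f), value = TRUE)
  expect_equal(f[inv], f_half[inv], tolerance = 1e-6)

  # missing payload: named missing values
  f_na <- extract_voice(NULL, "articulation")
  expect_length(f_na, 495)
  expect_true(all(is.na(f_na)))
  expect_true(all(startsWith(names(f_na), "articulation.")))
})

test_that("across-segment summaries collapse correctly for a stationary clip", {
  v <- synth_voice(140, 0.2, 0.1, 30, duration = 3, rate = 16000, seed = 7)
  f <- extract_voice(v, "phonation")
  # a stationary clip: segment f0 varies far less than f0 itself
  expect_lt(unname(f["phonation.seg.f0.sd"]) / unname(f["phonation.seg.f0.mean"]),
            0.05)
  expect_equal(unname(f["phonation.seg.f0.mean"]), 140, tolerance = 0.05)
  # duration of a fully voiced clip is close to the clip length
  expect_equal(unname(f["phonation.duration"]), 3, tolerance = 0.15)
})

test_that("injected jitter and HNR are recovered at study settings", {
  jit <- vapply(1:6, function(s) {
    v <- synth_voice(120, 1, 0.3, 20, duration = 3, rate = 32000, seed = s)
    pa <- digibm:::extract_periods(v$samples, v$rate, 120)
    unname(jitter(pa$periods_ms)["pct"])
  }, numeric(1))
  expect_lt(abs(mean(jit) - 1), 0.2)

  h <- vapply(1:6, function(s) {
    v <- synth_voice(120, 0.2, 0.1, 15, duration = 3, rate = 32000, seed = s + 20)
    hnr(v$samples, v$rate, 120)
  }, numeric(1))
  expect_lt(abs(mean(h) - 15), 3)
})

test_that("jitter presets separate cohorts through the extracted feature", {
  hi <- vapply(1:5, function(s) {
    v <- synth_voice(120, 2, 0.3, 20, duration = 2, rate = 16000, seed = s)
    unname(extract_voice(v, "phonation")["phonation.seg.jitter_pct.mean"])
  }, numeric(1))
  lo <- vapply(1:5, function(s) {
    v <- synth_voice(120, 0.5, 0.3, 20, duration = 2, rate = 16000, seed = s + 30)
    unname(extract_voice(v, "phonation")["phonation.seg.jitter_pct.mean"])
  }, numeric(1))
  expect_gt(mean(outer(hi, lo, ">")), 0.8) # univariate AUC
  expect_gt(mean(hi), mean(lo))
})
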