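test_that("univariate time-domain features: degenerate and sinusoid cases", {
  t <- seq(0, 10, by = 0.01)
  n <- length(t)
  const <- univariate_time_features(rep(1, n), rep(0, n), rep(0, n), t)
  expect_equal(unname(const["zcr"]), 0)
  expect_equal(unname(const["accel.sd"]), 0)
  expect_equal(unname(const[c("pathlen.accel", "pathlen.vel", "pathlen.pos")]),
               c(0, 0, 0))

  x <- sin(2 * pi * 5 * t)
  sine <- univariate_time_features(x, rep(0, n), rep(0, n), t)
  # two crossings per cycle: 100 crossings over 10 s -> rate 10/s
  expect_equal(unname(sine["zcr"]), 10, tolerance = 0.02)
  expect_equal(unname(sine["icross.median"]), 100, tolerance = 1)
  expect_error(univariate_time_features(1:2, 1:2, 1:2, c(0, 1)), "3 samples")
})

test_that("univariate time-domain features match a brute-force recomputation on noise", {
  set.seed(9)
  t <- seq(0, 5, by = 0.01)
  n <- length(t)
  a <- rnorm(n); v <- cumsum(a) / 100; p <- cumsum(v) / 100
  f <- univariate_time_features(a, v, p, t)
  expect_equal(unname(f["accel.sd"]), sd(a))
  expect_equal(unname(f["accel.iqr"]),
               unname(diff(quantile(a, c(0.25, 0.75)))))
  expect_equal(unname(f["vel.mean"]), mean(v))
  expect_equal(unname(f["vel.q3"]), unname(quantile(v, 0.75)))
  expect_equal(unname(f["pathlen.accel"]), sum(abs(diff(a))))
  xc <- a - mean(a)
  s <- sign(xc); s[s == 0] <- 1
  cr <- t[which(diff(s) != 0)]
  expect_equal(unname(f["zcr"]), length(cr) / diff(range(t)))
  ic <- diff(cr) * 1000
  expect_equal(unname(f["icross.mean"]), mean(ic))
  expect_equal(unname(f["icross.sd"]), sd(ic))
  expect_equal(length(f), 20)
})

test_that("multivariate time-domain features: 24 values, hull oracles", {
  t <- seq(0, 2, by = 0.05)
  n <- length(t)
  line <- integrate_kinematics(
    motion_trace(t, t, 2 * t, 3 * t, frame = "geospatial"))
  f_line <- multivariate_time_features(line)
  expect_length(f_line, 24)
  expect_equal(unname(f_line["accel.xy.hull"]), 0)
  expect_equal(unname(f_line["accel.xyz.hull"]), 0)

  set.seed(4)
  stack <- integrate_kinematics(
    motion_trace(seq(0, 0.6, 0.05), rnorm(13), rnorm(13), rnorm(13),
                 frame = "geospatial"))
  f <- multivariate_time_features(stack)
  m <- cbind(stack$accel$x, stack$accel$y, stack$accel$z)
  expect_equal(unname(f["accel.xyz.hull"]), brute_hull_area_3d(m),
               tolerance = 1e-9)
  expect_equal(unname(f["accel.xy.pathlen"]),
               sum(sqrt(rowSums(diff(m[, 1:2])^2))))
})

test_that("frequency-domain features: 49 values, band logic on pure tones", {
  t <- seq(0, 10, by = 0.01)
  f6 <- univariate_frequency_features(sin(2 * pi * 6 * t), 100)
  expect_length(f6, 49)
  tot <- sum(f6[grep("^band\\.[0-9]", names(f6))])
  expect_gt(unname(f6["band.5.5_6.5"]) / unname(f6["band.4_10"]), 0.99)
  expect_equal(unname(f6["rolloff.p50"]), 6, tolerance = 0.3)

  f2 <- univariate_frequency_features(sin(2 * pi * 2 * t), 100)
  full_psd <- welch_psd(sin(2 * pi * 2 * t), 100)
  expect_lt(unname(f2["band.4_10"]) / band_energy(full_psd, 0, 50.01), 0.01)
})

test_that("coherence features: 285 names, identical channels give coherence 1", {
  g <- synth_gait_trace(1.8, 40, seed = 6)
  rw <- rotate_to_geospatial(g$watch)
  rp <- rotate_to_geospatial(g$phone)
  sync <- synchronize(rw, rp)
  f <- coherence_features(sync$watch, sync$phone)
  expect_length(f, 285)
  expect_length(unique(names(f)), 285)
  # the watch x-channel paired with itself is not in the 15 pairs, so
  # check via msc directly that shared step clock drives cross-device
  # coherence near the gait frequency band
  pk <- f["watch.x_phone.z.peak_freq"]
  expect_lt(unname(pk), 15)
})

test_that("gait-event features: 51 values matching a windowing oracle", {
  g <- synth_gait_trace(1.8, 54, timing_jitter_sd = 0, seed = 9)
  rot <- rotate_to_geospatial(g$phone)
  stack <- integrate_kinematics(rot)
  steps <- detect_steps(rot)
  f <- gait_event_features(stack, steps, "z")
  expect_length(f, 51)
  expect_equal(unname(f["step_count"]), 54, tolerance = 1.01)
  dur <- diff(range(stack$accel$t))
  expect_equal(unname(f["step_freq"]), unname(f["step_count"]) / dur)
  # zero injected timing jitter: inter-step interval SD stays small
  expect_lt(unname(f["isi.sd"]) / unname(f["isi.mean"]), 0.05)
  # brute-force window oracle for one per-step quantity
  st <- steps$step_times
  t <- stack$accel$t
  isi <- vapply(seq_len(length(st) - 1), function(k) {
    (st[k + 1] - st[k]) * 1000
  }, numeric(1))
  expect_equal(unname(f["isi.mean"]), mean(isi))
  pl <- vapply(seq_len(length(st) - 1), function(k) {
    w <- which(t >= st[k] & t <= st[k + 1])
    sum(abs(diff(stack$accel$z[w])))
  }, numeric(1))
  expect_equal(unname(f["pathlen_accel.median"]), median(pl))
})

test_that("tremor extraction yields 462 uniquely named features; reversal invariance", {
  payload <- list(
    postural = synth_tremor_trace(0.04, 6, duration = 6, seed = 1),
    resting = synth_tremor_trace(0.03, 6, duration = 6, seed = 2))
  f <- extract_tremor(payload)
  expect_length(f, 462)
  expect_length(unique(names(f)), 462)
  expect_equal(sum(is.na(f)), 0)

  # time reversal leaves the acceleration-based zero-cross rate, band
  # energies and hull areas unchanged (velocity/position are integrals of
  # the path and are not reversal-invariant)
  tr <- payload$postural
  rev_tr <- motion_trace(tr$t, rev(tr$ax), rev(tr$ay), rev(tr$az))
  f_fwd <- extract_tremor(list(postural = tr, resting = tr))
  f_rev <- extract_tremor(list(postural = rev_tr, resting = rev_tr))
  exact <- grep("zcr|multi\\.accel\\..*\\.hull", names(f_fwd), value = TRUE)
  expect_equal(f_fwd[exact], f_rev[exact], tolerance = 1e-9)
  # band energies are reversal-invariant up to Welch segmentation edge
  # effects: compare on the scale of the total in-band power
  bands <- grep("freq\\.band\\.", names(f_fwd), value = TRUE)
  expect_lt(max(abs(f_fwd[bands] - f_rev[bands])) / sum(f_fwd[bands]), 1e-3)

  # missing sub-payload: names preserved, values missing
  half <- extract_tremor(list(postural = payload$postural))
  expect_length(half, 462)
  expect_equal(sum(is.na(half)), 231)
})

test_that("gait/balance extraction yields 2106 features and 1053-per-task accounting", {
  session <- full_session()
  f <- extract_gaitbalance(session$payloads$gait_balance)
  expect_length(f, 2106)
  expect_length(unique(names(f)), 2106)
  task <- sub("^gait_balance\\.([a-z]+)\\..*$", "\\1", names(f))
  expect_equal(as.integer(table(task)[c("balance", "gait")]), c(1053L, 1053L))

  # balance-only payload: gait names still emitted as missing
  only_bal <- extract_gaitbalance(list(balance = session$payloads$gait_balance$balance))
  expect_length(only_bal, 2106)
  expect_equal(sum(is.na(only_bal[grepl("^gait_balance\\.gait\\.", names(only_bal))])),
               1053)
})

test_that("tremor-band features separate high- from low-amplitude records", {
  hi <- vapply(1:8, function(s) {
    f <- extract_tremor(list(
      postural = synth_tremor_trace(0.05, 6, duration = 6, seed = s),
      resting = synth_tremor_trace(0.04, 6, duration = 6, seed = s + 50)))
    unname(f["tremor.postural.watch.x.freq.band.4_10"])
  }, numeric(1))
  lo <- vapply(1:8, function(s) {
    f <- extract_tremor(list(
      postural = synth_tremor_trace(0.004, 6, duration = 6, seed = s + 100),
      resting = synth_tremor_trace(0.003, 6, duration = 6, seed = s + 150)))
    unname(f["tremor.postural.watch.x.freq.band.4_10"])
  }, numeric(1))
  # univariate separation: every high-amplitude record outranks every low
  auc <- mean(outer(hi, lo, ">"))
  expect_gt(auc, 0.8)
})
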