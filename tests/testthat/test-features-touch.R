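test_that("tapping features: 28 values; metronomic and alternating cases", {
  taps <- synth_taps(mean_iti = 250, sd_iti = 0, n_taps = 60, spatial_sd = 0,
                     miss_prob = 0, seed = 1)
  payload <- list(dominant = taps, nondominant = taps)
  f <- tapping_features(payload)
  expect_length(f, 28)
  expect_length(unique(names(f)), 28)
  expect_equal(unname(f["finger_tapping.dominant.iti.median"]), 250)
  expect_equal(unname(f["finger_tapping.dominant.iti.iqr"]), 0)
  expect_equal(unname(f["finger_tapping.dominant.ratio"]), 1)
  expect_equal(unname(f["finger_tapping.dominant.peak_freq"]), 4,
               tolerance = 0.05)
})

test_that("tapping statistics equal a brute-force recomputation", {
  taps <- synth_taps(mean_iti = 200, sd_iti = 40, n_taps = 80, spatial_sd = 8,
                     seed = 3)
  f <- tapping_features(list(dominant = taps, nondominant = taps))
  downs <- taps[taps$phase == "down", ]
  expect_equal(unname(f["finger_tapping.dominant.total"]), nrow(downs))
  expect_equal(unname(f["finger_tapping.dominant.alternating"]),
               1 + sum(diff(downs$target_id) != 0))
  expect_equal(unname(f["finger_tapping.dominant.iti.median"]),
               median(diff(downs$t)))
  expect_equal(unname(f["finger_tapping.dominant.duration.median"]),
               median(downs$duration))
  targets <- attr(taps, "targets")
  d <- apply(cbind(downs$x, downs$y), 1, function(p) {
    min(sqrt((targets$x - p[1])^2 + (targets$y - p[2])^2))
  })
  expect_equal(unname(f["finger_tapping.dominant.distance.median"]), median(d))
})

test_that("fine-motor features: 19 values; ideal drag gives unit ratios", {
  clean <- synth_path("finemotor", tremor_amp = 0, seed = 2)
  payload <- list(dominant = list(log = clean, n_completed = 10),
                  nondominant = list(log = clean, n_completed = 8))
  f <- finemotor_features(payload)
  expect_length(f, 19)
  expect_equal(unname(f["fine_motor.summary.ratio"]), 10 / 8)
  expect_equal(unname(f["fine_motor.dominant.pathlen_ratio"]), 1,
               tolerance = 1e-6)
  expect_equal(unname(f["fine_motor.dominant.rotation_ratio"]), 1,
               tolerance = 1e-6)
  # no injected perturbation: negligible tremor-band energy relative to a
  # perturbed drag
  wob <- synth_path("finemotor", tremor_amp = 12, seed = 2)
  f_wob <- finemotor_features(list(dominant = list(log = wob, n_completed = 10),
                                   nondominant = list(log = wob, n_completed = 8)))
  expect_lt(unname(f["fine_motor.dominant.band4_10.vertical"]),
            0.01 * unname(f_wob["fine_motor.dominant.band4_10.vertical"]))
})

test_that("fine-motor tremor-band energy rises monotonically with amplitude", {
  e <- vapply(c(2, 6, 12), function(a) {
    log <- synth_path("finemotor", tremor_amp = a, tremor_freq = 6, seed = 5)
    f <- finemotor_features(list(dominant = list(log = log, n_completed = 1),
                                 nondominant = NULL))
    unname(f["fine_motor.dominant.band4_10.vertical"] +
             f["fine_motor.dominant.band4_10.horizontal"])
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("trails features: 12 values; RMSE oracle cases", {
  ideal_log <- synth_path("trails", tremor_amp = 0, seed = 4)
  payload <- list(A = ideal_log, B = ideal_log)
  f <- trails_features(payload)
  expect_length(f, 12)
  expect_equal(unname(f["trails.a.rmse"]), 0, tolerance = 1e-9)

  # constant perpendicular offset d from a single horizontal segment
  seg <- idealized_path(cbind(x = c(0, 100), y = c(0, 0)))
  pts <- tibble::tibble(t = seq(0, 1000, length.out = 40),
                        x = seq(5, 95, length.out = 40), y = 3,
                        phase = "move", hand = "dominant",
                        target_id = NA_integer_, duration = NA_real_)
  off_log <- structure(pts, ideal = seg,
                       class = c("touch_log", class(pts)))
  f_off <- trails_features(list(A = off_log, B = off_log))
  expect_equal(unname(f_off["trails.a.rmse"]), 3, tolerance = 1e-9)

  # noisy path: RMSE equals the brute-force point-to-segment oracle
  noisy <- synth_path("trails", tremor_amp = 7, seed = 6)
  ideal <- attr(noisy, "ideal")
  d <- point_to_path_distance(cbind(noisy$x, noisy$y), ideal)
  f_noisy <- trails_features(list(A = noisy, B = noisy))
  expect_equal(unname(f_noisy["trails.a.rmse"]), sqrt(mean(d^2)))
  expect_equal(unname(f_noisy["trails.a.pathlen"]),
               sum(sqrt(rowSums(diff(cbind(noisy$x, noisy$y))^2))))
})

test_that("VSTM capacity K and SDMT summaries follow their formulas", {
  perfect <- tibble::tibble(trial = 1:20, set_size = 4L,
                            change = rep(c(TRUE, FALSE), 10),
                            response_change = rep(c(TRUE, FALSE), 10),
                            correct = TRUE)
  f <- vstm_features(perfect)
  expect_equal(unname(f), c(1, 4))

  k_case <- function(hit, fa) {
    n <- 400
    change <- rep(c(TRUE, FALSE), each = n / 2)
    resp <- c(rep(c(TRUE, FALSE), c(hit * n / 2, (1 - hit) * n / 2)),
              rep(c(TRUE, FALSE), c(fa * n / 2, (1 - fa) * n / 2)))
    trials <- tibble::tibble(trial = 1:n, set_size = 4L, change = change,
                             response_change = resp,
                             correct = change == resp)
    unname(vstm_features(trials)["vstm.k"])
  }
  expect_equal(k_case(0.5, 0.5), 0)
  expect_equal(k_case(0.75, 0.25), 2)

  sd_trials <- synth_trials("sdmt", n_completed = 37, accuracy = 0.9, seed = 8)
  f_sd <- sdmt_features(sd_trials)
  expect_length(f_sd, 2)
  expect_equal(unname(f_sd["sdmt.total_completed"]), 37)
  expect_equal(unname(f_sd["sdmt.accuracy"]), mean(sd_trials$correct))
})
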