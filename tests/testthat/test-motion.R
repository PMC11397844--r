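test_that("motion traces drop and count non-finite rows, enforce monotone time", {
  tr <- motion_trace(c(0, 0.01, 0.02, 0.03), c(0, NA, 0, 0),
                     c(0, 1, 0, 0), c(-1, -1, -1, -1))
  expect_equal(nrow(tr), 3)
  expect_equal(attr(tr, "n_dropped"), 1)
  expect_error(motion_trace(c(0, 0.02, 0.01), 1:3, 1:3, 1:3),
               "strictly increasing")
})

test_that("rotation maps gravity onto z for canonical orientations", {
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  down <- rotate_to_geospatial(motion_trace(t, rep(0, n), rep(0, n), rep(-1, n)))
  expect_equal(abs(mean(down$az)), 1, tolerance = 1e-12)
  sideways <- rotate_to_geospatial(motion_trace(t, rep(-1, n), rep(0, n), rep(0, n)))
  expect_equal(abs(mean(sideways$az)), 1, tolerance = 1e-12)
  expect_lt(max(abs(sideways$ax), abs(sideways$ay)), 1e-12)
  expect_error(rotate_to_geospatial(motion_trace(t, rep(0, n), rep(0, n), rep(0, n))),
               "degenerate")
})

test_that("rotation is norm-preserving on a tilted oscillating trace", {
  t <- seq(0, 10, by = 0.01)
  tr <- motion_trace(t, 0.35 + 0.05 * sin(2 * pi * 5 * t),
                     rep(0.1, length(t)), rep(-0.93, length(t)))
  rot <- rotate_to_geospatial(tr)
  n_in <- sqrt(tr$ax^2 + tr$ay^2 + tr$az^2)
  n_out <- sqrt(rot$ax^2 + rot$ay^2 + rot$az^2)
  expect_lt(max(abs(n_in - n_out) / n_in), 1e-9)
  expect_equal(attr(rot, "frame"), "geospatial")
})

test_that("trapezoidal integration matches closed forms and is linear", {
  t <- seq(0, 5, by = 0.01)
  n <- length(t)
  const <- integrate_kinematics(
    motion_trace(t, rep(0.2, n), rep(0, n), rep(0, n), frame = "geospatial"))
  expect_equal(const$velocity$x[n], 0.2 * 5, tolerance = 1e-9)

  f <- 2
  sine <- integrate_kinematics(
    motion_trace(t, sin(2 * pi * f * t), rep(0, n), rep(0, n),
                 frame = "geospatial"))
  closed <- (1 - cos(2 * pi * f * t)) / (2 * pi * f)
  # trapezoid-rule error is O(dt^2): bounded by T * max|a''| * dt^2 / 12
  bound <- 5 * (2 * pi * f)^2 * 0.01^2 / 12
  expect_lt(max(abs(sine$velocity$x - closed)), bound)

  zero <- integrate_kinematics(
    motion_trace(t, rep(0, n), rep(0, n), rep(0, n), frame = "geospatial"))
  expect_true(all(zero$velocity$x == 0) && all(zero$position$x == 0))

  # linearity: integrate(a + b) = integrate(a) + integrate(b)
  a <- sin(2 * pi * 2 * t); b <- 0.3 * t
  both <- integrate_kinematics(
    motion_trace(t, a + b, rep(0, n), rep(0, n), frame = "geospatial"))
  ia <- integrate_kinematics(
    motion_trace(t, a, rep(0, n), rep(0, n), frame = "geospatial"))
  ib <- integrate_kinematics(
    motion_trace(t, b, rep(0, n), rep(0, n), frame = "geospatial"))
  expect_equal(both$velocity$x, ia$velocity$x + ib$velocity$x, tolerance = 1e-12)
  expect_error(integrate_kinematics(
    motion_trace(0, 1, 1, 1, frame = "geospatial")), "two samples")
})

test_that("synchronization aligns clocks and shortens to the overlap", {
  t <- seq(0, 10, by = 0.01)
  n <- length(t)
  w <- motion_trace(t, sin(2 * pi * 3 * t), rep(0, n), rep(-1, n))
  p <- motion_trace(t, sin(2 * pi * 3 * t), rep(0, n), rep(-1, n),
                    device = "phone")
  sync <- synchronize(w, p)
  expect_equal(sync$watch$ax, sync$phone$ax, tolerance = 1e-9)

  p_shift <- motion_trace(t + 0.5, sin(2 * pi * 3 * t), rep(0, n), rep(-1, n),
                          device = "phone")
  sync2 <- synchronize(w, p_shift)
  expect_equal(diff(range(sync2$watch$t)), 9.5, tolerance = 0.02)
  # after resampling onto the common clock, the shared sinusoid re-aligns:
  # cross-correlation peaks at lag 0
  cc <- stats::ccf(sync2$watch$ax - mean(sync2$watch$ax),
                   sync2$phone$ax - mean(sync2$phone$ax),
                   lag.max = 50, plot = FALSE)
  # phone content is the same sinusoid shifted by 0.5 s = 1.5 periods;
  # the envelope maximum must sit within one period of zero lag
  expect_lt(abs(cc$lag[which.max(abs(cc$acf))]), 34)
  expect_error(synchronize(w, motion_trace(t + 20, sin(t), rep(0, n),
                                           rep(-1, n), device = "phone")),
               "overlap")
})

test_that("step detection finds injected strikes and applies the exclusion rules", {
  flat <- motion_trace(seq(0, 6, 0.01), rep(0.01, 601), rep(0, 601),
                       rep(-1, 601), frame = "geospatial")
  expect_length(detect_steps(flat)$step_times, 0)

  for (cadence in c(1.2, 1.8, 2.2)) {
    g <- synth_gait_trace(cadence, 54, seed = 4)
    st <- detect_steps(rotate_to_geospatial(g$phone))
    truth <- attr(g, "step_times")
    expect_lte(abs(length(st$step_times) - 54), 1)
    # recall / precision >= 0.95 against injected strike times
    hits <- vapply(truth, function(s) any(abs(st$step_times - s) < 0.25),
                   logical(1))
    expect_gte(mean(hits), 0.95)
  }

  # two isolated transients 1.2 s apart: the second is excluded
  t <- seq(0, 6, by = 0.01)
  s <- numeric(length(t))
  for (st0 in c(2, 3.2)) {
    w <- which(abs(t - st0) < 0.06)
    s[w] <- s[w] + 0.8 * exp(-((t[w] - st0)^2) / (2 * 0.012^2))
  }
  set.seed(5)
  tr <- motion_trace(t, rnorm(length(t), sd = 0.004),
                     rnorm(length(t), sd = 0.004), -1 + s,
                     frame = "geospatial")
  st <- detect_steps(tr)
  expect_equal(st$excluded_count, 1)
  expect_equal(length(st$step_times), 1)
  expect_true(all(st$inter_step_intervals <= 1000))
})
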