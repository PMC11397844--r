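# Synthetic sensor-signal generators. These emulate the signal classes the
# feature catalog is designed to detect — tremor-band oscillations riding on
# gravity, impulse-like step transients with arm-swing, glottal pulse trains
# with controllable jitter/shimmer/HNR, tap renewal processes, and tremor-
# perturbed touch paths — with the injected parameters retained as ground
# truth for recovery tests. They make no claim of biomechanical realism.

# 1/f ("pink") noise via spectral shaping of white noise.
pink_noise <- function(n) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  Re(fft(sp / sqrt(f), inverse = TRUE)) / n
}

#' Synthesize a tremor accelerometry trace
#'
#' Gravity offset along a slightly tilted axis, plus a sinusoidal tremor
#' component at `freq` on an axis orthogonal to gravity, plus mixed white
#' and 1/f noise on every channel. In-band signal power scales with
#' `amplitude^2`.
#'
#' @param amplitude tremor amplitude in g (0 disables the oscillation)
#' @param freq tremor frequency in Hz, must lie in the 4-10 Hz band
#' @param noise_sd white-noise SD in g
#' @param duration record length in seconds
#' @param rate sampling rate in Hz
#' @param seed integer seed
#' @param device device tag for the trace
#' @param tilt_deg tilt of the gravity axis away from sensor z
#' @return a `motion_trace` in the device frame
#' @export
synth_tremor_trace <- function(amplitude, freq, noise_sd = 0.003,
                               duration = 10, rate = 100, seed = 1,
                               device = "watch", tilt_deg = 15) {
  if (amplitude > 0 && (freq < 4 || freq > 10)) {
    stop("tremor frequency must lie in the 4-10 Hz band")
  }
  with_seed_(check_seed(seed), {
    t <- seq(0, duration, by = 1 / rate)
    n <- length(t)
    th <- tilt_deg * pi / 180
    g <- c(sin(th), 0, -cos(th))
    trem_axis <- c(cos(th), 0, sin(th)) # orthogonal to gravity
    phase <- runif(1, 0, 2 * pi)
    osc <- amplitude * sin(2 * pi * freq * t + phase)
    a <- outer(rep(1, n), g) + outer(osc, trem_axis)
    for (j in 1:3) {
      a[, j] <- a[, j] + rnorm(n, sd = noise_sd) + 0.5 * noise_sd * pink_noise(n)
    }
    motion_trace(t, a[, 1], a[, 2], a[, 3], device = device, frame = "device")
  })
}

#' Synthesize a walking bout on watch and phone
#'
#' A shared step clock drives impulse-like transients (heel strikes) on the
#' phone (trunk) trace; the watch (wrist) trace carries attenuated strike
#' transients plus a sinusoidal arm-swing component at half the step
#' frequency scaled by `arm_swing_amp`. Because both devices share the step
#' clock, their cross-coherence peaks at the gait frequency.
#'
#' @param cadence steps per second
#' @param n_steps number of steps in the bout
#' @param arm_swing_amp arm-swing acceleration amplitude in g
#' @param step_amp strike transient amplitude in g
#' @param timing_jitter_sd SD of multiplicative inter-step timing noise
#' @param noise_sd white-noise SD in g
#' @param rate sampling rate in Hz
#' @param seed integer seed
#' @return list of `motion_trace` objects `watch` and `phone`, with the
#'   injected step times as attribute `step_times`
#' @export
synth_gait_trace <- function(cadence, n_steps, arm_swing_amp = 0.15,
                             step_amp = 0.6, timing_jitter_sd = 0.02,
                             noise_sd = 0.01, rate = 100, seed = 1) {
  with_seed_(check_seed(seed), {
    iti <- (1 / cadence) * (1 + timing_jitter_sd * rnorm(n_steps))
    iti <- pmax(iti, 0.2)
    step_times <- 0.5 + cumsum(iti)
    duration <- max(step_times) + 0.5
    t <- seq(0, duration, by = 1 / rate)
    n <- length(t)
    strike <- function(gain) {
      s <- numeric(n)
      for (st in step_times) {
        # narrow biphasic transient (~30 ms) so the 10-Hz high-pass keeps it
        w <- which(abs(t - st) < 0.06)
        s[w] <- s[w] + gain * (1 - ((t[w] - st) / 0.015)^2) *
          exp(-((t[w] - st)^2) / (2 * 0.012^2))
      }
      s
    }
    phone_z <- -1 + strike(step_amp) + rnorm(n, sd = noise_sd)
    phone <- motion_trace(t,
                          rnorm(n, sd = noise_sd),
                          rnorm(n, sd = noise_sd) + 0.3 * strike(step_amp),
                          phone_z, device = "phone", frame = "device")
    swing <- arm_swing_amp * sin(pi * cadence * t + runif(1, 0, 2 * pi))
    watch <- motion_trace(t,
                          swing + 0.2 * strike(step_amp) + rnorm(n, sd = noise_sd),
                          rnorm(n, sd = noise_sd),
                          -1 + 0.3 * strike(step_amp) + rnorm(n, sd = noise_sd),
                          device = "watch", frame = "device")
    structure(list(watch = watch, phone = phone), step_times = step_times)
  })
}

#' Synthesize a sustained-vowel voice clip
#'
#' A glottal pulse train with per-period length perturbation (jitter),
#' per-period amplitude perturbation (shimmer), a low-pass voiced spectral
#' envelope, and additive noise at the level implied by `hnr_db`. The
#' perturbation SDs are calibrated so that the injected `jitter_pct` /
#' `shimmer_db` equal the expected values of the local (cycle-to-cycle)
#' estimators the voice catalog computes.
#'
#' @param f0 fundamental frequency in Hz
#' @param jitter_pct target local jitter in percent
#' @param shimmer_db target local shimmer in dB
#' @param hnr_db target harmonic-to-noise ratio in dB (`Inf` for noiseless)
#' @param duration clip length in seconds
#' @param rate sampling rate in Hz
#' @param seed integer seed
#' @return an `audio_clip`: list with `samples` in \[-1, 1\] and `rate`
#' @export
synth_voice <- function(f0 = 120, jitter_pct = 0.5, shimmer_db = 0.3,
                        hnr_db = 20, duration = 15, rate = 32000, seed = 1) {
  with_seed_(check_seed(seed), {
    t0 <- 1 / f0
    n_periods <- ceiling(duration / t0) + 2
    # E|d_i - d_{i-1}| for iid N(0, s) differences is s*sqrt(2)*sqrt(2/pi)
    sj <- (jitter_pct / 100) / (sqrt(2) * sqrt(2 / pi))
    ss <- (shimmer_db / (20 / log(10))) / (sqrt(2) * sqrt(2 / pi))
    periods <- t0 * (1 + sj * rnorm(n_periods))
    periods <- pmax(periods, t0 * 0.5)
    amps <- exp(ss * rnorm(n_periods + 1)) # one per pulse onset
    onsets <- cumsum(c(0.01, periods))
    n <- round(duration * rate)
    x <- numeric(n)
    # fractional-sample pulse placement: split each impulse across the two
    # neighbouring samples so the period sequence is not quantized to the
    # sample grid
    pos <- onsets[onsets < duration] * rate
    k <- floor(pos) + 1
    frac <- pos - floor(pos)
    ok <- k >= 1 & k + 1 <= n
    k <- k[ok]; frac <- frac[ok]; a_ok <- amps[seq_along(ok)][ok]
    for (i in seq_along(k)) {
      x[k[i]] <- x[k[i]] + a_ok[i] * (1 - frac[i])
      x[k[i] + 1] <- x[k[i] + 1] + a_ok[i] * frac[i]
    }
    # voiced spectral envelope: two cascaded low-pass resonance-ish poles
    bt <- signal::butter(2, min(0.9, 2 * 1200 / rate), "low")
    x <- signal::filter(bt$b, bt$a, x)
    x <- as.numeric(x)
    if (is.finite(hnr_db)) {
      ps <- mean(x^2)
      x <- x + rnorm(n, sd = sqrt(ps / 10^(hnr_db / 10)))
    }
    x <- x / max(abs(x)) * 0.9
    audio_clip(x, rate)
  })
}

#' Construct an audio clip
#'
#' @param samples mono waveform in \[-1, 1\]
#' @param rate sampling rate in Hz
#' @return an `audio_clip` object
#' @export
audio_clip <- function(samples, rate) {
  stopifnot(is.numeric(samples), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate), class = "audio_clip")
}

#' Synthesize a finger-tapping touch log
#'
#' A renewal process alternating between two screen targets: inter-tap
#' intervals are `mean_iti + N(0, sd_iti)`, tap locations scatter around the
#' current target with isotropic SD `spatial_sd`, tap durations are drawn
#' around 80 ms.
#'
#' @param mean_iti mean inter-tap interval in ms
#' @param sd_iti SD of the inter-tap interval in ms
#' @param n_taps number of taps
#' @param spatial_sd tap-location scatter in px
#' @param hand `"dominant"` or `"nondominant"`
#' @param seed integer seed
#' @param miss_prob probability a tap lands on the non-alternating target
#' @return a `touch_log` tibble: `t` (ms), `x`, `y` (px), `phase`, `hand`,
#'   `target_id`, `duration` (ms), with target geometry as attribute
#' @export
synth_taps <- function(mean_iti = 200, sd_iti = 30, n_taps = 100,
                       spatial_sd = 6, hand = "dominant", seed = 1,
                       miss_prob = 0.02) {
  targets <- data.frame(target_id = c(1, 2), x = c(120, 260), y = c(420, 420))
  with_seed_(check_seed(seed), {
    iti <- pmax(mean_iti + sd_iti * rnorm(n_taps - 1), 40)
    onsets <- cumsum(c(200, iti))
    want <- rep_len(c(1, 2), n_taps)
    miss <- runif(n_taps) < miss_prob
    hit <- ifelse(miss, 3 - want, want)
    durations <- pmax(rnorm(n_taps, 80, 10), 20)
    xs <- targets$x[hit] + rnorm(n_taps, sd = spatial_sd)
    ys <- targets$y[hit] + rnorm(n_taps, sd = spatial_sd)
    down <- tibble::tibble(t = onsets, x = xs, y = ys, phase = "down",
                           hand = hand, target_id = hit, duration = durations)
    up <- dplyr::mutate(down, t = .data$t + .data$duration, phase = "up")
    log <- dplyr::arrange(dplyr::bind_rows(down, up), .data$t)
    structure(log, targets = targets, class = c("touch_log", class(log)))
  })
}

#' Synthesize a drawn touch path (trails or fine-motor drag)
#'
#' The pointer follows the idealized piecewise-linear segment chain between
#' target locations at constant speed, with a 4-10 Hz tremor-band
#' perturbation of amplitude `tremor_amp` px added perpendicular to the
#' path, sampled at an irregular touch-event rate.
#'
#' @param task `"trails"` or `"finemotor"`
#' @param tremor_amp tremor perturbation amplitude in px (0 for ideal path)
#' @param tremor_freq perturbation frequency in Hz (4-10)
#' @param speed drawing speed in px/s
#' @param event_rate mean touch-event rate in Hz
#' @param targets optional matrix/data frame of target x,y locations
#' @param hand hand label stored in the log
#' @param seed integer seed
#' @return a `touch_log` tibble of move events with attribute `ideal`
#'   (an `idealized_path`)
#' @export
synth_path <- function(task = c("trails", "finemotor"), tremor_amp = 0,
                       tremor_freq = 6, speed = NULL, event_rate = 24,
                       targets = NULL, hand = "dominant", seed = 1) {
  task <- match.arg(task)
  # drag-and-rotate is slower than trail drawing
  if (is.null(speed)) speed <- if (task == "trails") 600 else 150
  if (is.null(targets)) {
    targets <- if (task == "trails") {
      cbind(x = c(60, 300, 120, 330, 80, 280), y = c(80, 140, 300, 380, 500, 560))
    } else {
      cbind(x = c(80, 300), y = c(200, 420))
    }
  }
  ideal <- idealized_path(targets)
  with_seed_(check_seed(seed), {
    seg <- diff(as.matrix(targets))
    seg_len <- sqrt(rowSums(seg^2))
    total_len <- sum(seg_len)
    duration <- total_len / speed
    tt <- sort(c(0, runif(max(8, round(duration * event_rate)), 0, duration),
                 duration))
    s <- tt * speed # arc-length position
    pts <- arc_point(as.matrix(targets), seg, seg_len, s)
    if (tremor_amp > 0) {
      perp <- pts$perp
      wob <- tremor_amp * sin(2 * pi * tremor_freq * tt + runif(1, 0, 2 * pi))
      pts$x <- pts$x + perp[, 1] * wob
      pts$y <- pts$y + perp[, 2] * wob
    }
    log <- tibble::tibble(t = tt * 1000, x = pts$x, y = pts$y, phase = "move",
                          hand = hand, target_id = NA_integer_,
                          duration = NA_real_)
    ideal_rotation <- 90
    if (task == "finemotor") {
      # rotation channel: linear ramp to the target orientation plus the
      # same tremor-band wobble scaled down
      ang <- ideal_rotation * tt / duration
      if (tremor_amp > 0) {
        ang <- ang + 0.2 * tremor_amp * sin(2 * pi * tremor_freq * tt)
      }
      log$angle <- ang
    }
    structure(log, ideal = ideal, task = task, ideal_rotation = ideal_rotation,
              class = c("touch_log", class(log)))
  })
}

# Point on a piecewise-linear chain at arc lengths s, plus unit perpendiculars.
arc_point <- function(targets, seg, seg_len, s) {
  cum <- c(0, cumsum(seg_len))
  s <- pmin(pmax(s, 0), cum[length(cum)] - 1e-9)
  k <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[k]) / seg_len[k]
  dir <- seg / seg_len
  list(x = targets[k, 1] + frac * seg[k, 1],
       y = targets[k, 2] + frac * seg[k, 2],
       perp = cbind(-dir[k, 2], dir[k, 1]))
}

#' Idealized piecewise-linear reference path
#'
#' @param targets ordered target locations (two columns, px)
#' @return an `idealized_path` object
#' @export
idealized_path <- function(targets) {
  targets <- as.matrix(targets)
  if (nrow(targets) < 2) stop("an idealized path needs at least two targets")
  len <- sum(sqrt(rowSums(diff(targets)^2)))
  if (len <= 0) stop("idealized path length must be positive")
  structure(list(targets = targets, length = len), class = "idealized_path")
}

#' Synthesize a cognitive trial table
#'
#' Single-probe change-detection (VSTM, set size 4) or symbol-digit matching
#' (SDMT) trials with given response-accuracy parameters.
#'
#' @param task `"vstm"` or `"sdmt"`
#' @param n_trials number of trials
#' @param hit_rate,fa_rate VSTM hit and false-alarm probabilities
#' @param n_completed,accuracy SDMT totals
#' @param seed integer seed
#' @return a tibble of trials
#' @export
synth_trials <- function(task = c("vstm", "sdmt"), n_trials = 40,
                         hit_rate = 0.9, fa_rate = 0.1,
                         n_completed = 40, accuracy = 0.95, seed = 1) {
  task <- match.arg(task)
  with_seed_(check_seed(seed), {
    if (task == "vstm") {
      change <- rep_len(c(TRUE, FALSE), n_trials)
      said_change <- ifelse(change, runif(n_trials) < hit_rate,
                            runif(n_trials) < fa_rate)
      tibble::tibble(trial = seq_len(n_trials), set_size = 4L,
                     change = change, response_change = said_change,
                     correct = change == said_change)
    } else {
      tibble::tibble(trial = seq_len(n_completed),
                     correct = runif(n_completed) < accuracy)
    }
  })
}
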