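# Motion traces and the shared preprocessing used by the tremor and
# gait/balance catalogs: gravity-referenced rotation, trapezoidal
# integration to velocity and position, cross-device synchronization and
# FIR-based step detection.

#' Construct a motion trace
#'
#' A timestamped triaxial acceleration series from one device. Rows with
#' any non-finite channel value are dropped (and counted in the
#' `n_dropped` attribute); timestamps must be strictly increasing.
#'
#' @param t time in seconds
#' @param ax,ay,az acceleration in g units
#' @param device `"watch"` or `"phone"`
#' @param frame `"device"` (sensor axes) or `"geospatial"` (gravity on +z)
#' @return a tibble of class `motion_trace` with columns `t, ax, ay, az`
#' @export
motion_trace <- function(t, ax, ay, az, device = c("watch", "phone"),
                         frame = c("device", "geospatial")) {
  device <- match.arg(device)
  frame <- match.arg(frame)
  stopifnot(length(t) == length(ax), length(t) == length(ay), length(t) == length(az))
  ok <- is.finite(t) & is.finite(ax) & is.finite(ay) & is.finite(az)
  n_dropped <- sum(!ok)
  out <- tibble::tibble(t = t[ok], ax = ax[ok], ay = ay[ok], az = az[ok])
  if (nrow(out) >= 2 && any(diff(out$t) <= 0)) {
    stop("motion trace timestamps must be strictly increasing")
  }
  structure(out, device = device, frame = frame, n_dropped = n_dropped,
            class = c("motion_trace", class(out)))
}

trace_meta <- function(trace) {
  list(device = attr(trace, "device"), frame = attr(trace, "frame"))
}

accel_matrix <- function(trace) cbind(trace$ax, trace$ay, trace$az)

#' Rotate a device-frame trace into the geospatial frame
#'
#' Estimates the gravity direction as the mean of the low-pass-filtered
#' (0.3 Hz, zero-phase) acceleration and applies the minimal-angle (Rodrigues)
#' proper rotation taking that direction to the +z axis, so that after
#' rotation the z-axis is perpendicular to the surface plane. The rotation is
#' orthonormal with determinant +1 and preserves each sample's vector norm.
#'
#' @param trace a `motion_trace` in the device frame
#' @return a `motion_trace` in the geospatial frame
#' @export
rotate_to_geospatial <- function(trace) {
  if (attr(trace, "frame") != "device") stop("trace is already in the geospatial frame")
  a <- accel_matrix(trace)
  fs <- sampling_rate(trace$t)
  g <- if (nrow(a) > 400) {
    colMeans(apply(a, 2, fir_filter, fs = fs, cutoff = 0.3, type = "low"))
  } else {
    colMeans(a)
  }
  gn <- sqrt(sum(g^2))
  if (gn < 1e-8) stop("degenerate gravity estimate: acceleration is all zero")
  u <- g / gn
  z <- c(0, 0, sign(sum(u * c(0, 0, 1)) + 1e-15)) # map gravity to the nearer pole
  v <- crossp(u, z)
  s <- sqrt(sum(v^2))
  cth <- sum(u * z)
  R <- if (s < 1e-12) {
    diag(3) * ifelse(cth > 0, 1, 1) # already aligned
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  ar <- a %*% t(R)
  motion_trace(trace$t, ar[, 1], ar[, 2], ar[, 3],
               device = attr(trace, "device"), frame = "geospatial")
}

#' Integrate acceleration to velocity and position
#'
#' First and second cumulative trapezoidal integrals of the acceleration
#' series, using the actual (possibly uneven) timestamps; initial velocity
#' and position are zero. No drift correction is applied: path-length
#' features downstream operate on the raw integrals.
#'
#' @param trace a `motion_trace` in the geospatial frame
#' @return a `kinematic_stack`: list with tibbles `accel`, `velocity`,
#'   `position` (columns `t, x, y, z`) and the source metadata
#' @export
integrate_kinematics <- function(trace) {
  if (nrow(trace) < 2) stop("need at least two samples to integrate")
  t <- trace$t
  a <- accel_matrix(trace)
  v <- apply(a, 2, function(col) pracma::cumtrapz(t, col))
  p <- apply(v, 2, function(col) pracma::cumtrapz(t, col))
  as_k <- function(m) tibble::tibble(t = t, x = m[, 1], y = m[, 2], z = m[, 3])
  structure(list(accel = as_k(a), velocity = as_k(v), position = as_k(p),
                 device = attr(trace, "device"), frame = attr(trace, "frame")),
            class = "kinematic_stack")
}

#' Synchronize two motion traces onto a common uniform clock
#'
#' Both traces are linearly interpolated onto a shared uniform grid (default
#' 100 Hz) spanning the overlapping time interval.
#'
#' @param watch,phone `motion_trace` objects
#' @param fs target common rate in Hz
#' @return list of two `motion_trace` objects on the shared clock
#' @export
synchronize <- function(watch, phone, fs = 100) {
  lo <- max(min(watch$t), min(phone$t))
  hi <- min(max(watch$t), max(phone$t))
  if (hi <= lo) stop("traces have no temporal overlap")
  tt <- seq(lo, hi, by = 1 / fs)
  resamp <- function(tr) {
    motion_trace(tt,
                 approx(tr$t, tr$ax, xout = tt)$y,
                 approx(tr$t, tr$ay, xout = tt)$y,
                 approx(tr$t, tr$az, xout = tt)$y,
                 device = attr(tr, "device"), frame = attr(tr, "frame"))
  }
  list(watch = resamp(watch), phone = resamp(phone))
}

#' Detect foot strikes in an acceleration trace
#'
#' Pipeline: 10-Hz high-pass FIR on each axis, Euclidean modulus, 5-Hz
#' low-pass FIR, second time-derivative, then candidate samples exceeding
#' 1.15 x the mean of the rectified processed signal. Runs of consecutive
#' supra-threshold samples collapse to one step at the run's local maximum;
#' a 300-ms refractory period prevents double-counting a single strike.
#' Steps whose interval to the previous retained step exceeds 1000 ms are
#' excluded and counted.
#'
#' @param trace a `motion_trace` in the geospatial frame, >= 5 s long
#' @param threshold_factor relative threshold over the mean rectified
#'   processed signal (the "15% increase" rule)
#' @param refractory_s minimum separation between retained strikes
#' @return a `step_series`: list with `step_times` (s), `inter_step_intervals`
#'   (ms) and `excluded_count`
#' @export
detect_steps <- function(trace, threshold_factor = 1.15, refractory_s = 0.3) {
  fs <- sampling_rate(trace$t)
  if (diff(range(trace$t)) < 5) stop("step detection needs at least 5 s of signal")
  a <- accel_matrix(trace)
  hp <- apply(a, 2, fir_filter, fs = fs, cutoff = 10, type = "high")
  modulus <- sqrt(rowSums(hp^2))
  env <- fir_filter(modulus, fs, 5, "low")
  d2 <- c(0, 0, diff(env, differences = 2)) * fs^2
  ref <- mean(abs(d2))
  if (ref <= 0) {
    return(structure(list(step_times = numeric(0),
                          inter_step_intervals = numeric(0),
                          excluded_count = 0L), class = "step_series"))
  }
  above <- d2 > threshold_factor * ref
  # collapse runs of supra-threshold samples to their local maximum
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peaks <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    peaks <- c(peaks, seg[which.max(d2[seg])])
  }
  times <- trace$t[peaks]
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times <- times[keep]
  # drop steps more than 1000 ms after the previous retained step
  excluded <- 0L
  if (length(times) > 1) {
    retained <- times[1]
    for (i in 2:length(times)) {
      if ((times[i] - retained[length(retained)]) * 1000 > 1000) {
        excluded <- excluded + 1L
      } else {
        retained <- c(retained, times[i])
      }
    }
    times <- retained
  }
  structure(list(step_times = times,
                 inter_step_intervals = diff(times) * 1000,
                 excluded_count = excluded),
            class = "step_series")
}
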