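# Acoustic feature catalog for the sustained-phonation and syllable-
# repetition (articulation) tasks: the clip is divided into 15 equal
# segments; 38 base descriptors are computed per segment and summarized by
# 13 statistics across segments, plus total speech duration: 495 features.

VOICE_BANDS <- list(c(50, 80), c(80, 120), c(120, 200), c(200, 360),
                    c(360, 680), c(680, 1500), c(1500, 4000))
VOICE_BAND_NAMES <- c("50_80", "80_120", "120_200", "200_360",
                      "360_680", "680_1500", "1500_4000")
VOICE_STATS13 <- c("mean", "median", "q1", "q3", "iqr", "p1", "p99",
                   "iqr99", "sd", "kurtosis", "skewness", "flatness", "rms")

#' Estimate the fundamental frequency of a voiced segment
#'
#' Autocorrelation method with a 50-500 Hz search range; segments whose
#' peak normalized autocorrelation falls below the voicing threshold (or
#' that are essentially silent) return `NA`.
#'
#' @param x waveform segment
#' @param rate sampling rate in Hz
#' @param f_min,f_max search range in Hz
#' @param voicing_threshold minimum normalized autocorrelation peak
#' @return f0 in Hz, or `NA`
#' @export
estimate_f0 <- function(x, rate, f_min = 50, f_max = 500,
                        voicing_threshold = 0.3) {
  x <- x - mean(x)
  if (mean(x^2) < 1e-12) return(NA_real_)
  r <- norm_autocorr(x)
  lag_min <- max(2, floor(rate / f_max))
  lag_max <- min(length(r) - 1, ceiling(rate / f_min))
  if (lag_max <= lag_min) return(NA_real_)
  seg <- r[(lag_min + 1):(lag_max + 1)]
  k <- which.max(seg)
  if (seg[k] < voicing_threshold) return(NA_real_)
  lag <- lag_min + k - 1
  # parabolic interpolation around the peak for sub-sample lag precision
  if (lag > lag_min && lag < lag_max) {
    y1 <- r[lag]; y2 <- r[lag + 1]; y3 <- r[lag + 2]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
  }
  rate / lag
}

norm_autocorr <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(Mod(sp)^2, inverse = TRUE))[1:n] / nfft
  ac / ac[1]
}

#' Cycle-to-cycle period perturbation (jitter)
#'
#' Local jitter: the mean absolute difference between consecutive periods,
#' in ms and as a percentage of the mean period.
#'
#' @param periods_ms sequence of glottal period lengths in ms
#' @return named vector `c(ms, pct)`
#' @export
jitter <- function(periods_ms) {
  if (length(periods_ms) < 2) return(c(ms = NA_real_, pct = NA_real_))
  ms <- mean(abs(diff(periods_ms)))
  c(ms = ms, pct = 100 * ms / mean(periods_ms))
}

#' Cycle-to-cycle amplitude perturbation (shimmer)
#'
#' Local shimmer: in dB, the mean absolute base-20 log ratio of consecutive
#' peak amplitudes; in percent, the mean absolute consecutive amplitude
#' difference relative to the mean amplitude.
#'
#' @param amplitudes per-cycle peak amplitudes
#' @return named vector `c(db, pct)`
#' @export
shimmer <- function(amplitudes) {
  if (length(amplitudes) < 2 || any(amplitudes <= 0)) {
    return(c(db = NA_real_, pct = NA_real_))
  }
  c(db = mean(abs(20 * log10(amplitudes[-1] / amplitudes[-length(amplitudes)]))),
    pct = 100 * mean(abs(diff(amplitudes))) / mean(amplitudes))
}

#' Harmonic-to-noise ratio of a voiced segment
#'
#' Autocorrelation method: with r the peak normalized autocorrelation at
#' the fundamental period lag, HNR = 10 log10(r / (1 - r)).
#'
#' @param x waveform segment
#' @param rate sampling rate in Hz
#' @param f0 fundamental frequency (estimated if `NULL`)
#' @return HNR in dB, or `NA` for unvoiced segments
#' @export
hnr <- function(x, rate, f0 = NULL) {
  if (is.null(f0)) f0 <- estimate_f0(x, rate)
  if (is.na(f0)) return(NA_real_)
  x <- x - mean(x)
  r <- norm_autocorr(x)
  n <- length(x)
  lag0 <- rate / f0
  lo <- max(2, floor(lag0 * 0.9)); hi <- min(length(r) - 1, ceiling(lag0 * 1.1))
  lags <- lo:hi
  # undo the finite-window taper bias n/(n - lag) before the peak search
  rmax <- max(r[lags + 1] * n / (n - lags))
  rmax <- min(max(rmax, 1e-12), 1 - 1e-12)
  10 * log10(rmax / (1 - rmax))
}

# Glottal period and amplitude extraction: band-pass around f0, upward
# zero crossings mark cycle boundaries; per-cycle peak |amplitude| from
# the raw waveform.
extract_periods <- function(x, rate, f0) {
  lo <- max(0.6 * f0, 30) / (rate / 2)
  hi <- min(1.5 * f0, rate / 2 * 0.95) / (rate / 2)
  bf <- signal::butter(2, c(lo, hi), "pass")
  xf <- signal::filtfilt(bf$b, bf$a, x)
  s <- sign(xf)
  up <- which(diff(s) > 0) # upward crossings
  if (length(up) < 3) return(NULL)
  # linear interpolation of the crossing instant
  tc <- (up + xf[up] / (xf[up] - xf[up + 1])) / rate
  periods <- diff(tc)
  amps <- vapply(seq_len(length(up) - 1), function(k) {
    max(abs(x[up[k]:up[k + 1]]))
  }, numeric(1))
  keep <- periods > 0.5 / f0 & periods < 2 / f0
  periods <- periods[keep]; amps <- amps[keep]
  # the outermost cycles sit in the band-pass filter's edge transient and
  # report spurious period perturbation; drop two from each end
  if (length(periods) > 8) {
    sel <- 3:(length(periods) - 2)
    periods <- periods[sel]; amps <- amps[sel]
  }
  list(periods_ms = periods * 1000, amplitudes = amps)
}

#' Per-segment spectral descriptors of a voice segment
#'
#' Seven band energies (50-4000 Hz), five whole-spectrum statistics
#' (flatness, entropy, variance, skewness, kurtosis), four roll-offs
#' (25/50/75/90%) and MFCC 1-16.
#'
#' @param x waveform segment
#' @param rate sampling rate in Hz
#' @return named numeric vector of length 32
#' @export
voice_spectral_features <- function(x, rate) {
  psd <- welch_psd(x, rate, seg_len = min(length(x), round(rate / 10)))
  bands <- vapply(VOICE_BANDS, function(b) band_energy(psd, b[1], b[2]), numeric(1))
  names(bands) <- paste0("band.", VOICE_BAND_NAMES)
  sstats <- c(flatness = spectral_flatness(psd$power),
              entropy = spectral_entropy(psd$power),
              variance = var(psd$power),
              skewness = skewness_(psd$power),
              kurtosis = kurtosis_(psd$power))
  ro <- vapply(c(25, 50, 75, 90), function(p) spectral_rolloff(psd, p), numeric(1))
  names(ro) <- paste0("rolloff.p", c(25, 50, 75, 90))
  mf <- mfcc_from_psd(psd, n_coef = 16, n_filters = 32, fmin = 0,
                      fmax = min(4000, rate / 2))
  c(bands, setNames(sstats, paste0("spec.", names(sstats))), ro, mf)
}

voice_descriptor_names <- function() {
  c("f0", "hnr", "jitter_ms", "jitter_pct", "shimmer_db", "shimmer_pct",
    paste0("band.", VOICE_BAND_NAMES),
    paste0("spec.", c("flatness", "entropy", "variance", "skewness", "kurtosis")),
    paste0("rolloff.p", c(25, 50, 75, 90)),
    paste0("mfcc", 1:16))
}

segment_descriptors <- function(x, rate) {
  f0 <- estimate_f0(x, rate)
  jit <- c(ms = NA_real_, pct = NA_real_)
  shi <- c(db = NA_real_, pct = NA_real_)
  h <- NA_real_
  if (!is.na(f0)) {
    pa <- extract_periods(x, rate, f0)
    if (!is.null(pa) && length(pa$periods_ms) >= 3) {
      jit <- jitter(pa$periods_ms)
      shi <- shimmer(pa$amplitudes)
    }
    h <- hnr(x, rate, f0)
  }
  c(f0 = f0, hnr = h, jitter_ms = unname(jit["ms"]), jitter_pct = unname(jit["pct"]),
    shimmer_db = unname(shi["db"]), shimmer_pct = unname(shi["pct"]),
    voice_spectral_features(x, rate))
}

# Thirteen NA-skipping summary statistics across the 15 segment values.
# Flatness (geometric/arithmetic mean) is computed on absolute values;
# kurtosis/skewness of a constant vector are defined as 0 so a fully
# voiced stationary clip emits no missing summaries.
voice_stats13 <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(na_like(VOICE_STATS13))
  p1 <- unname(quantile(v, 0.01)); p99 <- unname(quantile(v, 0.99))
  kur <- kurtosis_(v); ske <- skewness_(v)
  if (length(v) > 1 && sd(v) == 0) { kur <- 0; ske <- 0 }
  c(mean = mean(v), median = median(v), q1 = q1(v), q3 = q3(v), iqr = iqr_(v),
    p1 = p1, p99 = p99, iqr99 = p99 - p1,
    sd = if (length(v) > 1) sd(v) else 0,
    kurtosis = kur, skewness = ske,
    flatness = if (mean(abs(v)) > 0) geometric_mean(abs(v)) / mean(abs(v)) else NA_real_,
    rms = sqrt(mean(v^2)))
}

#' Total speech duration by short-time energy endpointing
#'
#' 25-ms frames; frames whose energy exceeds -25 dB relative to the peak
#' frame count as speech.
#'
#' @param clip an `audio_clip`
#' @param frame_s frame length in seconds
#' @param threshold_db threshold below the peak frame energy
#' @return speech duration in seconds
#' @export
speech_duration <- function(clip, frame_s = 0.025, threshold_db = -25) {
  n <- length(clip$samples)
  flen <- max(1, round(frame_s * clip$rate))
  nf <- floor(n / flen)
  if (nf == 0) return(0)
  e <- vapply(seq_len(nf), function(k) {
    mean(clip$samples[((k - 1) * flen + 1):(k * flen)]^2)
  }, numeric(1))
  peak <- max(e)
  if (peak <= 0) return(0)
  sum(10 * log10(e / peak) > threshold_db) * flen / clip$rate
}

#' Extract the acoustic feature set from a voice clip
#'
#' Total speech duration plus 13 summary statistics over the 15-segment
#' values of each of 38 per-segment descriptors: 495 features. The same
#' catalog is applied to phonation and articulation clips.
#'
#' @param clip an `audio_clip` (or `NULL` for a missing payload)
#' @param task `"phonation"` or `"articulation"`; used as the name prefix
#' @return named numeric vector of length 495
#' @export
extract_voice <- function(clip, task = c("phonation", "articulation")) {
  task <- match.arg(task)
  descr <- voice_descriptor_names()
  nm <- c(paste0(task, ".duration"),
          as.vector(t(outer(descr, VOICE_STATS13,
                            function(d, s) paste0(task, ".seg.", d, ".", s)))))
  if (is.null(clip)) return(na_like(nm))
  n <- length(clip$samples)
  edges <- floor(seq(0, n, length.out = 16))
  segvals <- matrix(NA_real_, nrow = 15, ncol = length(descr),
                    dimnames = list(NULL, descr))
  for (k in 1:15) {
    seg <- clip$samples[(edges[k] + 1):edges[k + 1]]
    segvals[k, ] <- segment_descriptors(seg, clip$rate)
  }
  out <- numeric(0)
  for (d in descr) out <- c(out, voice_stats13(segvals[, d]))
  setNames(c(speech_duration(clip), out), nm)
}
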