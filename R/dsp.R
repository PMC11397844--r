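# Spectral estimation primitives shared by the motion, voice and touch
# feature catalogs.

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window and 50% overlap. The
#' density is one-sided and scaled so that `sum(psd) * df` approximates the
#' variance of the (mean-removed) signal.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param seg_len segment length in samples; defaults to `fs * 5` capped at
#'   the record length (so a 10-s record is analysed as two segments)
#' @param overlap fractional overlap between segments
#' @param demean remove the segment mean before windowing
#' @return tibble with columns `frequency` (Hz) and `power` (density)
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("signal too short for spectral estimation")
  if (is.null(seg_len)) seg_len <- min(n, round(fs * 5))
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seg_starts(n, seg_len, step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  u <- sum(w^2)
  nfreq <- floor(seg_len / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    if (demean) seg <- seg - mean(seg)
    sp <- fft(seg * w)[seq_len(nfreq)]
    acc <- acc + (Mod(sp)^2) / (u * fs)
  }
  psd <- acc / length(starts)
  # fold the two-sided density into one side (DC/Nyquist not doubled)
  if (seg_len %% 2 == 0) {
    psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  } else {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  tibble::tibble(frequency = (seq_len(nfreq) - 1) * fs / seg_len, power = psd)
}

# Segment starts covering the whole record: the usual overlapped grid plus
# a final tail-flush segment when the grid does not reach the end.
seg_starts <- function(n, seg_len, step) {
  starts <- seq(1, n - seg_len + 1, by = step)
  last <- n - seg_len + 1
  if (starts[length(starts)] < last) starts <- c(starts, last)
  starts
}

# Cross-spectral Welch estimate used by magnitude-squared coherence.
welch_cross <- function(x, y, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seg_starts(n, seg_len, step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nfreq <- floor(seg_len / 2) + 1
  pxx <- numeric(nfreq); pyy <- numeric(nfreq); pxy <- complex(nfreq)
  for (s in starts) {
    sx <- x[s:(s + seg_len - 1)]; sx <- (sx - mean(sx)) * w
    sy <- y[s:(s + seg_len - 1)]; sy <- (sy - mean(sy)) * w
    fx <- fft(sx)[seq_len(nfreq)]; fy <- fft(sy)[seq_len(nfreq)]
    pxx <- pxx + Mod(fx)^2
    pyy <- pyy + Mod(fy)^2
    pxy <- pxy + fx * Conj(fy)
  }
  list(frequency = (seq_len(nfreq) - 1) * fs / seg_len,
       pxx = pxx, pyy = pyy, pxy = pxy, n_seg = length(starts))
}

#' Magnitude-squared coherence between two synchronized signals
#'
#' @inheritParams welch_psd
#' @param y second signal, same length and clock as `x`
#' @return tibble with columns `frequency` and `coherence` in \[0, 1\]
#' @export
msc_coherence <- function(x, y, fs, seg_len = NULL, overlap = 0.5) {
  if (length(x) != length(y)) stop("signals must share a common clock")
  if (is.null(seg_len)) seg_len <- min(length(x), round(fs * 5))
  cs <- welch_cross(x, y, fs, seg_len, overlap)
  coh <- Mod(cs$pxy)^2 / pmax(cs$pxx * cs$pyy, .Machine$double.xmin)
  tibble::tibble(frequency = cs$frequency, coherence = pmin(coh, 1))
}

#' Spectral band energy
#'
#' Integral of the PSD over `[lo, hi)` (trapezoid-free bin sum times the
#' frequency resolution), matching a partition-additivity property: band
#' energies over a partition of the axis sum to total power.
#'
#' @param psd tibble from [welch_psd()]
#' @param lo,hi band edges in Hz
#' @return scalar energy
#' @export
band_energy <- function(psd, lo, hi) {
  df <- psd$frequency[2] - psd$frequency[1]
  sum(psd$power[psd$frequency >= lo & psd$frequency < hi]) * df
}

#' Spectral roll-off
#'
#' Lowest frequency below which `p` percent of the total spectral power lies.
#'
#' @param psd tibble from [welch_psd()]
#' @param p percentage in (0, 100)
#' @return frequency in Hz
#' @export
spectral_rolloff <- function(psd, p) {
  cum <- cumsum(psd$power)
  tot <- cum[length(cum)]
  if (tot <= 0) return(NA_real_)
  psd$frequency[which(cum >= p / 100 * tot)[1]]
}

# Shannon entropy of the PSD normalised to a probability mass function
# (natural log); flatness = geometric / arithmetic mean.
spectral_entropy <- function(power) {
  p <- power[power > 0]
  if (length(p) == 0) return(NA_real_)
  p <- p / sum(p)
  -sum(p * log(p))
}

spectral_flatness <- function(power) {
  power <- power[is.finite(power) & power >= 0]
  if (length(power) == 0 || mean(power) <= 0) return(NA_real_)
  geometric_mean(power) / mean(power)
}

# Five-stat distributional summary of a spectral view (vector of PSD
# ordinates): entropy, SD, kurtosis, skewness, flatness.
spectral_view_stats <- function(power) {
  c(entropy = spectral_entropy(power),
    sd = if (length(power) > 1) sd(power) else NA_real_,
    kurtosis = kurtosis_(power),
    skewness = skewness_(power),
    flatness = spectral_flatness(power))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters mel-spaced over `[fmin, fmax]`, evaluated at the PSD
#' bin frequencies.
#'
#' @param freqs PSD bin frequencies (Hz)
#' @param n_filters number of triangular filters
#' @param fmin,fmax filterbank range (Hz)
#' @return `n_filters` x `length(freqs)` matrix
#' @keywords internal
mel_filterbank <- function(freqs, n_filters = 32, fmin = 0, fmax = max(freqs)) {
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2))
  fb <- matrix(0, n_filters, length(freqs))
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; cen <- edges[i + 1]; hi <- edges[i + 2]
    up <- (freqs - lo) / max(cen - lo, 1e-12)
    dn <- (hi - freqs) / max(hi - cen, 1e-12)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Mel-frequency cepstral coefficients from a PSD
#'
#' Log mel filterbank energies followed by an orthonormal DCT-II; the 0th
#' (overall-level) coefficient is excluded, so the result is scale-invariant
#' in the waveform amplitude.
#'
#' @param psd tibble from [welch_psd()]
#' @param n_coef number of coefficients to return (1..n_coef)
#' @param n_filters number of mel filters
#' @param fmin,fmax analysis range in Hz
#' @return named numeric vector `mfcc1..mfccN`
#' @export
mfcc_from_psd <- function(psd, n_coef = 16, n_filters = 32,
                          fmin = 0, fmax = max(psd$frequency)) {
  keep <- psd$frequency <= fmax
  fb <- mel_filterbank(psd$frequency[keep], n_filters, fmin, fmax)
  e <- as.numeric(fb %*% psd$power[keep])
  loge <- log(pmax(e, 1e-300))
  k <- seq_len(n_coef)
  m <- length(loge)
  dct <- sqrt(2 / m) * cos(outer(k, seq_len(m) - 0.5, function(kk, nn) pi * kk * nn / m))
  setNames(as.numeric(dct %*% loge), paste0("mfcc", k))
}

# Linear-phase windowed-sinc FIR (Hamming), applied forward-backward for
# zero phase. `type` is "low" or "high"; cutoff in Hz.
fir_filter <- function(x, fs, cutoff, type = c("low", "high"), order = 100) {
  type <- match.arg(type)
  wc <- cutoff / (fs / 2)
  if (wc >= 1) return(x)
  b <- as.numeric(signal::fir1(order, wc, type))
  pad <- min(length(x) - 1, 3 * order)
  # reflect-pad to limit end transients of the zero-phase pass
  xx <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  yy <- signal::filtfilt(b, 1, xx)
  yy[(pad + 1):(pad + length(x))]
}

# Resample an irregular series onto a uniform clock by linear interpolation.
resample_uniform <- function(t, x, fs) {
  if (length(t) < 2) stop("need at least two samples to resample")
  tt <- seq(min(t), max(t), by = 1 / fs)
  approx(t, x, xout = tt, rule = 2)$y
}
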