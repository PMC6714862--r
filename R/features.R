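#' Canonical EEG rhythm bands
#'
#' Frequency intervals (Hz) for the four rhythms used throughout the
#' pipeline: theta 3-7, alpha 8-13, beta 14-29, gamma 30-47.
#'
#' @return named list of `c(low, high)` pairs.
#' @export
rhythm_bands <- function() {
  list(theta = c(3, 7), alpha = c(8, 13), beta = c(14, 29), gamma = c(30, 47))
}

#' Zero-phase band-pass filtering of one channel
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and ~unit passband gain.
#'
#' @param x numeric vector, one channel of one trial.
#' @param fs sampling rate in Hz.
#' @param band `c(low, high)` in Hz; must lie strictly inside `(0, fs/2)`.
#' @param order filter order (default 4).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_rhythm <- function(x, fs, band, order = 4) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("`band` must be c(low, high) with 0 < low < high")
  if (band[2] >= fs / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band[2], fs / 2))
  if (length(x) < 3L * (order + 1L))
    stop("signal too short for the filter warm-up")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Hjorth parameters
#'
#' Time-domain descriptors of a signal: activity (variance, population
#' convention), mobility (square root of the ratio of the first difference's
#' variance to the signal's variance), and complexity (the mobility of the
#' first difference divided by the mobility of the signal).  A constant
#' signal returns `(0, 0, 0)` by convention.
#'
#' @param x numeric vector of length at least 3.
#' @return named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth_parameters <- function(x) {
  if (length(x) < 3L) stop("hjorth_parameters() needs at least 3 samples")
  v0 <- pop_var(x)
  if (v0 == 0)
    return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x)
  v1 <- pop_var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0)
    return(c(activity = v0, mobility = 0, complexity = 0))
  d2 <- diff(d1)
  mob1 <- sqrt(pop_var(d2) / v1)
  c(activity = v0, mobility = mob, complexity = mob1 / mob)
}

# population variance (denominator n)
pop_var <- function(x) {
  m <- mean(x)
  sum((x - m)^2) / length(x)
}

#' Standard deviation of a signal
#'
#' Population convention by default (denominator `n`); set
#' `population = FALSE` for the sample convention (`n - 1`).
#'
#' @param x numeric vector of length at least 2.
#' @param population logical; divide by `n` (default) or `n - 1`.
#' @return non-negative scalar.
#' @export
signal_sd <- function(x, population = TRUE) {
  if (length(x) < 2L) stop("signal_sd() needs at least 2 samples")
  if (population) sqrt(pop_var(x)) else stats::sd(x)
}

# Welch power-spectral-density estimate: Hann-windowed segments, mean
# detrended, 50% overlap by default, one-sided density scaling so that
# sum(psd) * df ~ signal power.  Matches the usual scipy/matlab conventions.
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nper <- as.integer(round(seg_s * fs))
  n <- length(x)
  if (n < nper)
    stop(sprintf("signal (%d samples) shorter than one Welch segment (%d)",
                 n, nper))
  step <- nper - as.integer(floor(nper * overlap))
  starts <- seq.int(1L, n - nper + 1L, by = step)
  k <- seq_len(nper) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / nper))      # periodic Hann
  u <- fs * sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / u
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nper, psd = psd * dbl)
}

#' Mean band power from a Welch PSD estimate
#'
#' Averages the Welch power-spectral-density estimate over the frequency
#' bins falling inside `band` (inclusive edges).  Units are
#' (signal unit)^2 / Hz.  With the 2-s default segment the bin spacing is
#' 0.5 Hz, comfortably resolving the 3-7 Hz theta band on 60-s trials.
#'
#' @inheritParams bandpass_rhythm
#' @param seg_s Welch segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return non-negative scalar.
#' @export
psd_band_power <- function(x, fs, band, seg_s = 2, overlap = 0.5) {
  est <- welch_psd(x, fs, seg_s, overlap)
  sel <- est$freq >= band[1] & est$freq <= band[2]
  if (!any(sel))
    stop(sprintf("no PSD bin falls inside [%g, %g] Hz at resolution %g Hz",
                 band[1], band[2], est$freq[2] - est$freq[1]))
  mean(est$psd[sel])
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B counts template pairs (i != j) of
#' length `m` within Chebyshev distance `r` and A counts the same pairs at
#' length `m + 1`; self-matches are excluded (Richman-Moorman convention).
#' The tolerance defaults to `0.2 * sd(x)` (population sd).  A constant
#' signal returns 0; when no length-`m + 1` pair matches (A = 0) the
#' infinite value is capped at `log(B) + log(n)` so downstream matrices
#' stay finite.
#'
#' @param x numeric vector of length at least `m + 2`.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * signal_sd(x)`.
#' @return non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r = NULL) {
  n <- length(x)
  if (n < m + 2L) stop("sample_entropy() needs at least m + 2 samples")
  s <- signal_sd(x)
  if (s == 0) return(0)
  if (is.null(r)) r <- 0.2 * s
  if (r <= 0) stop("tolerance r must be positive")
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  a <- cnt[1L]; b <- cnt[2L]
  if (b == 0) return(2 * log(n))          # no template matches at all
  if (a == 0) return(log(b) + log(n))     # capped infinity
  -log(a / b)
}

# --- discrete wavelet transform (periodized Daubechies) ------------------

# Decomposition low-pass filters; high-pass follows by the quadrature
# mirror relation hi[k] = (-1)^(k+1) lo[L-1-k] (0-based).
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852,
          0.030841381835560764, -0.18703481171909309,
          -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

# one level of the periodized DWT: circular convolution + dyadic decimation
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  L <- length(lo)
  off <- L %/% 2L
  half <- n %/% 2L
  idx <- outer(2 * seq_len(half) - 2 + off, seq_len(L) - 1L, `-`) %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = as.numeric(xm %*% lo), d = as.numeric(xm %*% hi))
}

#' Relative wavelet energy distribution
#'
#' Decomposes the signal with a periodized Daubechies DWT (`db4`, 4 levels
#' by default), giving `levels + 1` components (the final approximation plus
#' each detail level), and returns each component's share of the total
#' energy.  The shares are non-negative and sum to 1.
#'
#' @param x numeric vector; length must be at least `2^levels`.
#' @param levels decomposition depth (default 4).
#' @param family `"db4"`, `"db2"` or `"db1"`.
#' @param zero treatment of an all-zero signal: `"error"` (default) or
#'   `"uniform"` (return the uniform distribution).
#' @return numeric vector of `levels + 1` relative energies, ordered from
#'   the deepest approximation to the first detail level.
#' @export
wavelet_energy_distribution <- function(x, levels = 4, family = "db4",
                                        zero = c("error", "uniform")) {
  zero <- match.arg(zero)
  lo <- .db_filters[[family]]
  if (is.null(lo)) stop("unknown wavelet family: ", family)
  if (length(x) < 2^levels)
    stop(sprintf("signal too short for %d decomposition levels", levels))
  hi <- rev(lo) * (-1)^(seq_along(lo))   # (-1)^(k+1) lo[L-1-k], 0-based
  e_detail <- numeric(levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, lo, hi)
    e_detail[j] <- sum(st$d^2)
    a <- st$a
  }
  energies <- c(sum(a^2), rev(e_detail))  # [A_L, D_L, ..., D_1]
  tot <- sum(energies)
  if (tot == 0) {
    if (zero == "error") stop("degenerate energy: all-zero signal")
    return(rep(1 / (levels + 1), levels + 1))
  }
  energies / tot
}

#' Shannon entropy of an energy distribution
#'
#' `-sum(p * log(p))` with `0 * log(0) = 0`; maximal (`log(length(p))`) for
#' the uniform distribution, 0 when the energy sits in one component.
#'
#' @param p non-negative weights summing to 1.
#' @return scalar in `[0, log(length(p))]`.
#' @export
energy_entropy <- function(p) {
  if (any(p < -1e-12)) stop("negative energy share")
  if (abs(sum(p) - 1) > 1e-9) stop("energy shares must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p)) + 0   # + 0 avoids IEEE negative zero for one-point masses
}

#' Wavelet entropy of a signal
#'
#' Shannon entropy of the relative wavelet energy distribution across the
#' DWT components (see [wavelet_energy_distribution()]): an ordered,
#' narrow-band signal concentrates energy in few components (entropy near 0),
#' broadband disorder spreads it (entropy near `log(levels + 1)`).
#'
#' @inheritParams wavelet_energy_distribution
#' @return scalar in `[0, log(levels + 1)]`.
#' @export
wavelet_entropy <- function(x, levels = 4, family = "db4",
                            zero = c("error", "uniform")) {
  energy_entropy(wavelet_energy_distribution(x, levels, family, zero))
}
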