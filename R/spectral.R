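# Multitaper front end.
#
# DPSS (Slepian) tapers are computed from the classic symmetric tridiagonal
# eigenproblem: diag_i = ((N-1-2i)/2)^2 cos(2*pi*W), offdiag_i = i(N-i)/2.
# The top eigenvectors are the tapers. Results are memoized per (N, nw).

.songvar_env <- new.env(parent = emptyenv())

dpss_tapers <- function(n, k = 2, nw = 1.5) {
  key <- sprintf("dpss_%d_%d_%g", n, k, nw)
  cached <- get0(key, .songvar_env)
  if (!is.null(cached)) return(cached)
  w <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- diag(d)
  m[cbind(1:(n - 1), 2:n)] <- e
  m[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(m, symmetric = TRUE)
  tapers <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0 || (j > 1 && v[2] - v[1] < 0)) v <- -v
    tapers[, j] <- v
  }
  assign(key, tapers, .songvar_env)
  tapers
}

#' Multitaper spectral frames with derivative spectra
#'
#' Computes a multitaper power spectrogram of a syllable segment plus
#' time- and frequency-derivative spectra (central finite differences on the
#' frame/bin grid) used by the frequency-modulation feature. Defaults follow
#' SAP-style analysis: 9.27 ms window, ~1.36 ms advance, 2 tapers.
#'
#' @param wave numeric waveform segment.
#' @param fs sampling rate (Hz).
#' @param window_ms analysis window (ms).
#' @param hop_ms frame advance (ms).
#' @param n_tapers number of DPSS tapers.
#' @param nfft FFT length (>= 2x window samples for clean autocorrelation).
#' @param band analysis band (Hz) for band-limited features.
#' @return object of class `spectral_frames`: list with `S` (band power,
#'   bins x frames), `Pfull` (full nfft power, for cepstrum/autocorrelation),
#'   `freq`, `times`, `dSdt`, `dSdf`, `fs`, `nfft`, `band`, `flagged`.
#' @export
spectral_frames <- function(wave, fs, window_ms = 9.27, hop_ms = 1.36,
                            n_tapers = 2, nfft = 1024, band = c(430, fs / 2)) {
  w <- round(window_ms * fs / 1000)
  h <- max(round(hop_ms * fs / 1000), 1)
  flagged <- FALSE
  if (length(wave) < w) {
    wave <- c(wave, numeric(w - length(wave)))  # zero-pad a short segment
    flagged <- TRUE
  }
  if (nfft < 2 * w) nfft <- 2^ceiling(log2(2 * w))
  n_frames <- floor((length(wave) - w) / h) + 1
  starts <- (seq_len(n_frames) - 1) * h + 1
  tapers <- dpss_tapers(w, k = n_tapers)
  frames <- vapply(starts, function(s) wave[s:(s + w - 1)], numeric(w))
  frames <- matrix(frames, nrow = w)
  p_full <- matrix(0, nrow = nfft, ncol = n_frames)
  for (k in seq_len(n_tapers)) {
    padded <- rbind(frames * tapers[, k],
                    matrix(0, nrow = nfft - w, ncol = n_frames))
    x <- stats::mvfft(padded)
    p_full <- p_full + Mod(x)^2
  }
  p_full <- p_full / n_tapers
  n_bins <- nfft / 2 + 1
  freq <- (0:(n_bins - 1)) * fs / nfft
  in_band <- freq >= band[1] & freq <= band[2]
  s_band <- p_full[seq_len(n_bins), , drop = FALSE][in_band, , drop = FALSE]
  d_dt <- matrix(0, nrow = nrow(s_band), ncol = n_frames)
  if (n_frames >= 3) {
    d_dt[, 2:(n_frames - 1)] <-
      (s_band[, 3:n_frames, drop = FALSE] -
         s_band[, 1:(n_frames - 2), drop = FALSE]) / 2
  }
  nb <- nrow(s_band)
  d_df <- matrix(0, nrow = nb, ncol = n_frames)
  if (nb >= 3) {
    d_df[2:(nb - 1), ] <- (s_band[3:nb, , drop = FALSE] -
                             s_band[1:(nb - 2), , drop = FALSE]) / 2
  }
  structure(list(S = s_band, Pfull = p_full, freq = freq[in_band],
                 times = (starts - 1) / fs, dSdt = d_dt, dSdf = d_df,
                 fs = fs, nfft = nfft, band = band,
                 window_samples = w, n_tapers = n_tapers,
                 flagged = flagged),
            class = "spectral_frames")
}

#' Wiener entropy of a power spectrum
#'
#' Log ratio of the geometric to the arithmetic mean of spectral power:
#' 0 for an exactly flat spectrum, increasingly negative for tonal sounds.
#' Invariant to global amplitude scaling.
#'
#' @param p non-negative power spectrum vector (already band-limited).
#' @return log ratio <= 0, or `NA` (flagged via attribute) for an all-zero
#'   spectrum.
#' @export
wiener_entropy <- function(p) {
  if (all(p == 0)) {
    return(structure(NA_real_, flagged = TRUE))
  }
  p <- p / max(p)
  p <- pmax(p, 1e-300)
  min(mean(log(p)) - log(mean(p)), 0)
}

#' Power-weighted mean frequency (spectral centroid)
#'
#' @param p power spectrum vector.
#' @param freq matching frequency vector (Hz).
#' @return centroid in Hz, or flagged `NA` for zero total power.
#' @export
mean_frequency <- function(p, freq) {
  tot <- sum(p)
  if (tot <= 0) return(structure(NA_real_, flagged = TRUE))
  sum(p * freq) / tot
}

# lag range (samples) corresponding to a fundamental search band in Hz
lag_range <- function(fs, search, nfft) {
  lmin <- max(floor(fs / search[2]), 2)
  lmax <- min(ceiling(fs / search[1]), floor(nfft / 2) - 1)
  c(lmin, lmax)
}

parabolic_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(i)
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

#' Cepstral pitch goodness of one spectral frame
#'
#' Height of the real-cepstrum peak over quefrencies corresponding to
#' fundamentals in `search` (Hz). Amplitude-scale invariant (the log spectrum
#' shifts by a constant, which only affects quefrency zero); non-negative.
#'
#' @param frames a [spectral_frames()] object.
#' @param j frame index.
#' @param search fundamental search range (Hz).
#' @return non-negative cepstral peak height.
#' @export
pitch_goodness <- function(frames, j = 1, search = c(300, 1500)) {
  p <- frames$Pfull[, j]
  if (all(p == 0)) return(0)
  cep <- Re(stats::fft(log(pmax(p, max(p) * 1e-12)), inverse = TRUE)) /
    frames$nfft
  lr <- lag_range(frames$fs, search, frames$nfft)
  max(max(cep[(lr[1]:lr[2]) + 1]), 0)
}

# mean autocorrelation of the analysis tapers, for lag-window debiasing
taper_lag_window <- function(w, k, nfft) {
  key <- sprintf("tlw_%d_%d_%d", w, k, nfft)
  cached <- get0(key, .songvar_env)
  if (!is.null(cached)) return(cached)
  tapers <- dpss_tapers(w, k)
  acc <- numeric(nfft)
  for (i in seq_len(k)) {
    X <- stats::fft(c(tapers[, i], numeric(nfft - w)))
    acc <- acc + Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  }
  acc <- acc / acc[1]
  assign(key, acc, .songvar_env)
  acc
}

# normalized autocorrelation of a frame via Wiener-Khinchin on the
# zero-padded power spectrum, debiased by the tapers' own lag window so a
# pure tone's peak sits at its true period
frame_autocorr <- function(frames, j) {
  ac <- Re(stats::fft(frames$Pfull[, j], inverse = TRUE)) / frames$nfft
  if (ac[1] <= 0) return(NULL)
  w <- taper_lag_window(frames$window_samples, frames$n_tapers, frames$nfft)
  ac <- ac / pmax(abs(w), 0.05)
  ac / ac[1]
}

#' Fundamental-frequency (pitch) estimate of one spectral frame
#'
#' Autocorrelation peak within the lag band implied by `search`, refined by
#' parabolic interpolation, used when the frame is harmonic enough
#' (pitch goodness above `goodness_threshold`); otherwise the mean frequency
#' of the frame is returned — the conventional noisy-frame fallback.
#'
#' @param frames a [spectral_frames()] object.
#' @param j frame index.
#' @param search search range (Hz).
#' @param goodness_threshold harmonicity gate; default is the 90th
#'   percentile of the pitch-goodness distribution on white-noise frames
#'   (from the package's seeded calibration corpus). A frame also counts as
#'   periodic when its normalized autocorrelation peak exceeds
#'   `quality_floor` — this covers single-component tones, whose cepstral
#'   peak is weak even though the period is unambiguous.
#' @param quality_floor minimum autocorrelation peak height.
#' @return estimated pitch in Hz.
#' @export
pitch <- function(frames, j = 1, search = c(300, 1500),
                  goodness_threshold = NULL, quality_floor = 0.3) {
  if (is.null(goodness_threshold)) {
    goodness_threshold <- similarity_calibration()$goodness_threshold
  }
  pg <- pitch_goodness(frames, j, search)
  ac <- frame_autocorr(frames, j)
  if (is.null(ac)) return(mean_frequency(frames$S[, j], frames$freq))
  lr <- lag_range(frames$fs, search, frames$nfft)
  lags <- lr[1]:lr[2]
  acl <- ac[lags + 1]
  # a periodic frame peaks at every multiple of its period; choose the
  # smallest lag among near-maximal local peaks to avoid octave-down errors
  peak_max <- max(acl)
  is_peak <- c(FALSE, acl[-c(1, length(acl))] > acl[-((length(acl) - 1):
                                                        length(acl))] &
                 acl[-c(1, length(acl))] >= acl[-(1:2)], FALSE)
  cand <- lags[is_peak & acl >= 0.85 * peak_max]
  i <- if (length(cand)) cand[1] else lags[which.max(acl)]
  quality <- ac[i + 1]
  if (pg < goodness_threshold && quality < quality_floor) {
    return(mean_frequency(frames$S[, j], frames$freq))
  }
  lag_star <- parabolic_peak(ac, i + 1) - 1
  frames$fs / lag_star
}

#' Frequency modulation of one spectral frame (degrees)
#'
#' Ratio of time-derivative to frequency-derivative spectral magnitude over
#' the frame's peak bins, mapped through arctangent to [0, 90] degrees.
#' A stationary tone gives ~0 deg; fast sweeps give large angles.
#'
#' @param frames a [spectral_frames()] object.
#' @param j frame index.
#' @param peak_frac bins with power >= `peak_frac` x frame max are used.
#' @return FM angle in degrees in [0, 90].
#' @export
frequency_modulation <- function(frames, j = 1, peak_frac = 0.5) {
  p <- frames$S[, j]
  if (max(p) <= 0) return(0)
  sel <- p >= peak_frac * max(p)
  td <- sum(abs(frames$dSdt[sel, j]))
  fd <- sum(abs(frames$dSdf[sel, j]))
  if (td == 0 && fd == 0) return(0)
  atan2(td, fd) * 180 / pi
}
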