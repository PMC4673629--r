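# Fundamental-frequency estimation and its rendition-to-rendition CV,
# the harmonic-stack variability measure used for social-context
# comparisons.

#' Estimate the fundamental frequency of a harmonic syllable
#'
#' A single analysis window (default 16 ms) is placed at a fixed fractional
#' offset of the syllable (default midpoint). FF is the inverse lag of the
#' highest normalized autocorrelation peak within the lag band implied by
#' `search_range`, refined by parabolic interpolation. The peak height is
#' the quality score; measurements below `quality_floor` are flagged
#' invalid and excluded from CV computation.
#'
#' @param wave syllable waveform.
#' @param fs sampling rate (Hz).
#' @param window_ms analysis window length (ms).
#' @param at fractional position of the window center within the syllable.
#' @param search_range FF search range (Hz).
#' @param quality_floor minimum normalized autocorrelation peak height.
#' @return one-row data.frame: `ff` (Hz, `NA` when invalid), `quality`,
#'   `valid`.
#' @export
estimate_ff <- function(wave, fs, window_ms = 16, at = 0.5,
                        search_range = c(300, 1500), quality_floor = 0.3) {
  w <- round(window_ms * fs / 1000)
  n <- length(wave)
  if (n < w) {
    return(data.frame(ff = NA_real_, quality = 0, valid = FALSE))
  }
  center <- round(at * n)
  i0 <- min(max(center - floor(w / 2), 1), n - w + 1)
  x <- wave[i0:(i0 + w - 1)]
  x <- x - mean(x)
  if (sum(x^2) == 0) {
    return(data.frame(ff = NA_real_, quality = 0, valid = FALSE))
  }
  nfft <- 2^ceiling(log2(2 * w))
  X <- stats::fft(c(x, numeric(nfft - w)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  ac <- ac / ac[1]
  lmin <- max(floor(fs / search_range[2]), 2)
  lmax <- min(ceiling(fs / search_range[1]), w - 2)
  lags <- lmin:lmax
  i <- lags[which.max(ac[lags + 1])]
  quality <- ac[i + 1]
  if (!is.finite(quality) || quality < quality_floor) {
    return(data.frame(ff = NA_real_, quality = max(quality, 0),
                      valid = FALSE))
  }
  lag_star <- parabolic_peak(ac, i + 1) - 1
  data.frame(ff = fs / lag_star, quality = quality, valid = TRUE)
}

#' Coefficient of variation of fundamental frequency across renditions
#'
#' Sample (n-1) standard deviation divided by the mean over valid FF
#' measurements. Invariant to global pitch transposition.
#'
#' @param ff numeric vector of FF values (NA = invalid, dropped).
#' @param warn_below warn when fewer renditions than this are available
#'   (the standard series uses 20).
#' @return non-negative unitless CV, or `NA` with fewer than 2 valid values.
#' @export
ff_cv <- function(ff, warn_below = 20) {
  ff <- ff[is.finite(ff)]
  if (length(ff) < 2) {
    warning("fewer than 2 valid FF measurements; CV undefined")
    return(NA_real_)
  }
  if (length(ff) < warn_below) {
    warning(sprintf("only %d valid FF measurements (< %d)", length(ff),
                    warn_below))
  }
  stats::sd(ff) / mean(ff)
}

#' Harmonic-stack eligibility for FF analysis
#'
#' A syllable qualifies when its mean frequency modulation is low
#' (< `fm_max` degrees) and its pitch goodness clears the harmonicity
#' threshold — the operational version of "low frequency-modulation
#' syllables with a clear fundamental".
#'
#' @param features one-row feature data.frame from [syllable_features()].
#' @param fm_max maximum mean FM (degrees).
#' @param goodness_threshold harmonicity threshold; defaults to the
#'   calibration gate used by [pitch()].
#' @return logical.
#' @export
harmonic_stack_eligible <- function(features, fm_max = 15,
                                    goodness_threshold = NULL) {
  if (is.null(goodness_threshold)) {
    goodness_threshold <- similarity_calibration()$goodness_threshold
  }
  features$frequency_modulation < fm_max &
    features$pitch_goodness > goodness_threshold
}
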