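# Per-frame feature extraction and rendition self-similarity scoring.

# Per-frame feature table for one segment: pitch, pitch goodness, Wiener
# entropy (signed), FM, mean frequency, band power.
frame_features <- function(frames, search = c(300, 1500),
                           goodness_threshold = NULL) {
  if (is.null(goodness_threshold)) {
    goodness_threshold <- similarity_calibration()$goodness_threshold
  }
  n <- ncol(frames$S)
  out <- data.frame(time = frames$times[seq_len(n)],
                    pitch = numeric(n), pitch_goodness = numeric(n),
                    wiener_entropy = numeric(n),
                    frequency_modulation = numeric(n),
                    mean_frequency = numeric(n), power = numeric(n))
  for (j in seq_len(n)) {
    out$pitch_goodness[j] <- pitch_goodness(frames, j, search)
    out$pitch[j] <- pitch(frames, j, search, goodness_threshold)
    out$wiener_entropy[j] <- as.numeric(wiener_entropy(frames$S[, j]))
    out$frequency_modulation[j] <- frequency_modulation(frames, j)
    out$mean_frequency[j] <- as.numeric(mean_frequency(frames$S[, j],
                                                       frames$freq))
    out$power[j] <- sum(frames$S[, j])
  }
  out
}

#' Per-syllable acoustic feature vector
#'
#' Duration comes from the segment bounds; spectral features are
#' amplitude(power)-weighted means of the per-frame values over the
#' syllable, which suppresses onset/offset ramp artifacts. Wiener entropy is
#' kept signed here; reporting code takes its magnitude.
#'
#' @param wave waveform of one syllable rendition.
#' @param fs sampling rate (Hz).
#' @param ... passed to [spectral_frames()].
#' @return one-row data.frame: `duration_ms`, `pitch`, `pitch_goodness`,
#'   `wiener_entropy` (signed, <= 0), `frequency_modulation`,
#'   `mean_frequency`, `amplitude` (dBFS RMS).
#' @export
syllable_features <- function(wave, fs, ...) {
  frames <- spectral_frames(wave, fs, ...)
  ff <- frame_features(frames)
  w <- ff$power
  if (sum(w) <= 0) w <- rep(1, nrow(ff))
  wmean <- function(x) sum(x * w, na.rm = TRUE) / sum(w[!is.na(x)])
  data.frame(duration_ms = length(wave) / fs * 1000,
             pitch = wmean(ff$pitch),
             pitch_goodness = wmean(ff$pitch_goodness),
             wiener_entropy = wmean(ff$wiener_entropy),
             frequency_modulation = wmean(ff$frequency_modulation),
             mean_frequency = wmean(ff$mean_frequency),
             amplitude = 10 * log10(max(mean(wave^2), 1e-12)))
}

#' Similarity calibration corpus
#'
#' Builds (once per session, from a fixed internal seed) the empirical
#' reference used by [self_similarity()] and the harmonicity gate of
#' [pitch()]: feature scales, the distribution of frame distances between
#' unrelated synthetic sounds, and the white-noise pitch-goodness
#' distribution whose 90th percentile gates cepstral pitch.
#'
#' @param fs sampling rate of the calibration corpus (Hz).
#' @return list with `sds` (per-feature scales), `dist` (sorted unrelated
#'   frame distances), `goodness_threshold`.
#' @export
similarity_calibration <- function(fs = 44100) {
  cached <- get0("calibration", .songvar_env)
  if (!is.null(cached)) return(cached)
  cal <- with_seed(903411L, {
    jit <- jitter_model(cv_f0 = 0, cv_duration = 0, cv_amplitude = 0)
    sounds <- list(
      synthesize_syllable(syllable_archetype("harmonic_stack", f0 = 450,
                                             duration_ms = 80), jit, fs, 1)$wave,
      synthesize_syllable(syllable_archetype("harmonic_stack", f0 = 750,
                                             duration_ms = 80), jit, fs, 2)$wave,
      synthesize_syllable(syllable_archetype("harmonic_stack", f0 = 1200,
                                             duration_ms = 80), jit, fs, 3)$wave,
      synthesize_syllable(syllable_archetype("fm_sweep", f_start = 900,
                                             f_end = 4500,
                                             duration_ms = 80), jit, fs, 4)$wave,
      synthesize_syllable(syllable_archetype("fm_sweep", f_start = 4000,
                                             f_end = 1500,
                                             duration_ms = 80), jit, fs, 5)$wave,
      synthesize_syllable(syllable_archetype("noise_burst",
                                             band = c(1000, 9000),
                                             duration_ms = 80), jit, fs, 6)$wave,
      db_to_linear(-20) * stats::rnorm(round(0.08 * fs))
    )
    # white-noise goodness distribution for the harmonicity gate
    noise_pg <- unlist(lapply(1:8, function(i) {
      fr <- spectral_frames(db_to_linear(-20) * stats::rnorm(round(0.06 * fs)),
                            fs)
      vapply(seq_len(ncol(fr$S)), function(j) pitch_goodness(fr, j),
             numeric(1))
    }))
    goodness_threshold <- stats::quantile(noise_pg, 0.9, names = FALSE)
    feats <- lapply(sounds, function(s) {
      fr <- spectral_frames(s, fs)
      ff <- frame_features(fr, goodness_threshold = goodness_threshold)
      as.matrix(ff[, c("pitch", "frequency_modulation", "wiener_entropy",
                       "pitch_goodness")])
    })
    pooled <- do.call(rbind, feats)
    sds <- apply(pooled, 2, stats::sd)
    sds[sds == 0] <- 1
    n_pairs <- 4000
    src <- sample(length(feats), n_pairs, replace = TRUE)
    dst <- sample(length(feats), n_pairs, replace = TRUE)
    keep <- src != dst
    d <- mapply(function(a, b) {
      fa <- feats[[a]][sample(nrow(feats[[a]]), 1), ] / sds
      fb <- feats[[b]][sample(nrow(feats[[b]]), 1), ] / sds
      sqrt(sum((fa - fb)^2))
    }, src[keep], dst[keep])
    list(sds = sds, dist = sort(d), goodness_threshold = goodness_threshold)
  })
  assign("calibration", cal, .songvar_env)
  cal
}

# distance -> similarity %: the percentage of unrelated-sound frame pairs
# whose distance exceeds d. Identical frames (d = 0) map to 100.
similarity_percent <- function(d, cal) {
  n <- length(cal$dist)
  100 * (n - findInterval(d, cal$dist)) / n
}

#' Self-similarity and accuracy of two renditions
#'
#' Frames of `a` (the reference) and `b` are compared in the scaled space of
#' (pitch, FM, Wiener entropy, pitch goodness). Distances convert to
#' percentages against the calibration distribution of unrelated-sound frame
#' distances. Accuracy is the mean frame similarity along the best monotone
#' (dynamic-time-warping) alignment; similarity is the percentage of
#' reference frames whose best local-neighborhood match exceeds
#' `threshold`.
#'
#' @param a,b waveforms of the two renditions (`a` is the reference).
#' @param fs sampling rate (Hz).
#' @param threshold local-match cutoff (percent) for the similarity score.
#' @param neighborhood frames searched around the aligned position.
#' @return list with `similarity` and `accuracy`, both in [0, 100].
#' @export
self_similarity <- function(a, b, fs, threshold = 50, neighborhood = 3) {
  cal <- similarity_calibration(fs)
  fa <- frame_features(spectral_frames(a, fs))
  fb <- frame_features(spectral_frames(b, fs))
  cols <- c("pitch", "frequency_modulation", "wiener_entropy",
            "pitch_goodness")
  ma <- sweep(as.matrix(fa[, cols]), 2, cal$sds, "/")
  mb <- sweep(as.matrix(fb[, cols]), 2, cal$sds, "/")
  n <- nrow(ma); m <- nrow(mb)
  if (n == 0 || m == 0) {
    return(structure(list(similarity = NA_real_, accuracy = NA_real_),
                     flagged = TRUE))
  }
  d <- matrix(0, n, m)
  for (i in seq_len(n)) {
    d[i, ] <- sqrt(colSums((t(mb) - ma[i, ])^2))
  }
  # monotone alignment (DTW, unit steps)
  acc <- matrix(Inf, n, m)
  acc[1, 1] <- d[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1) best <- min(best, acc[i - 1, j])
      if (j > 1) best <- min(best, acc[i, j - 1])
      if (i > 1 && j > 1) best <- min(best, acc[i - 1, j - 1])
      acc[i, j] <- d[i, j] + best
    }
  }
  # backtrack
  path <- list(c(n, m))
  i <- n; j <- m
  while (i > 1 || j > 1) {
    cands <- list()
    if (i > 1 && j > 1) cands <- c(cands, list(c(i - 1, j - 1)))
    if (i > 1) cands <- c(cands, list(c(i - 1, j)))
    if (j > 1) cands <- c(cands, list(c(i, j - 1)))
    vals <- vapply(cands, function(c2) acc[c2[1], c2[2]], numeric(1))
    step <- cands[[which.min(vals)]]
    path <- c(path, list(step))
    i <- step[1]; j <- step[2]
  }
  path <- do.call(rbind, rev(path))
  accuracy <- mean(similarity_percent(d[path], cal))
  # local-neighborhood similarity for each reference frame
  aligned_j <- vapply(seq_len(n), function(i2) {
    hits <- path[path[, 1] == i2, 2]
    hits[1]
  }, numeric(1))
  local_ok <- vapply(seq_len(n), function(i2) {
    jj <- max(1, aligned_j[i2] - neighborhood):min(m, aligned_j[i2] + neighborhood)
    max(similarity_percent(d[i2, jj], cal)) > threshold
  }, logical(1))
  list(similarity = 100 * mean(local_ok), accuracy = accuracy)
}

#' Mean consecutive-pair self-accuracy of a rendition series
#'
#' The series-level stereotypy score: [self_similarity()] applied to
#' consecutive rendition pairs (rendition r as reference for r+1), averaged.
#'
#' @param waves list of rendition waveforms, in rendition order.
#' @param fs sampling rate (Hz).
#' @param ... passed to [self_similarity()].
#' @return list with mean `similarity` and `accuracy`.
#' @export
series_self_accuracy <- function(waves, fs, ...) {
  stopifnot(length(waves) >= 2)
  scores <- lapply(seq_len(length(waves) - 1), function(i) {
    self_similarity(waves[[i]], waves[[i + 1]], fs, ...)
  })
  list(similarity = mean(vapply(scores, `[[`, numeric(1), "similarity")),
       accuracy = mean(vapply(scores, `[[`, numeric(1), "accuracy")))
}
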