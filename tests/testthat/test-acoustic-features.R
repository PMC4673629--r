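fs <- 44100

test_that("spectral frames locate pure tones and chirps correctly", {
  tone <- 0.3 * sin(2 * pi * 1000 * (0:8819) / fs)
  fr <- spectral_frames(tone, fs)
  peaks <- fr$freq[apply(fr$S, 2, which.max)]
  # peak localized within the multitaper design bandwidth (NW/N * fs ~ 160 Hz)
  expect_true(all(abs(peaks - 1000) < 170))

  t <- (0:8819) / fs
  chirp <- 0.3 * sin(2 * pi * (1000 * t + (4000 - 1000) * t^2 / (2 * max(t))))
  frc <- spectral_frames(chirp, fs)
  peaks_c <- frc$freq[apply(frc$S, 2, which.max)]
  inner <- peaks_c[3:(length(peaks_c) - 2)]
  # ridge increases across frames (up to bandwidth-scale jitter)
  expect_gt(cor(seq_along(inner), inner, method = "spearman"), 0.95)
  expect_gt(inner[length(inner)] - inner[1], 2000)

  # white noise: frame-averaged spectrum flat within 3 dB across the band
  set.seed(5)
  fn <- spectral_frames(0.2 * rnorm(fs / 2), fs)
  avg <- rowMeans(fn$S)
  smooth <- stats::filter(10 * log10(avg), rep(1 / 31, 31))
  smooth <- smooth[!is.na(smooth)]
  expect_lt(max(smooth) - min(smooth), 3)

  # segment shorter than one window is zero-padded and flagged
  short <- spectral_frames(tone[1:100], fs)
  expect_true(short$flagged)
  expect_equal(ncol(short$S), 1)
})

test_that("Wiener entropy is zero on flat spectra, low on tones, near zero on noise", {
  expect_identical(wiener_entropy(rep(7.5, 256)), 0)
  # constructed two-level near-tonal spectrum: closed form
  p <- c(rep(1, 255), 1e6)
  gm <- exp(mean(log(p))); am <- mean(p)
  expect_equal(wiener_entropy(p), log(gm / am), tolerance = 1e-12)
  expect_lt(wiener_entropy(p), -4)
  expect_true(is.na(wiener_entropy(numeric(10))))  # all-zero: flagged NA
  set.seed(6)
  fr <- spectral_frames(0.2 * rnorm(fs / 2), fs)
  wes <- vapply(seq_len(ncol(fr$S)), function(j) {
    as.numeric(wiener_entropy(fr$S[, j]))
  }, numeric(1))
  expect_lt(abs(mean(wes)), 0.5)
  expect_true(all(wes <= 0))
  # amplitude-scale invariance
  expect_equal(wiener_entropy(3 * p), wiener_entropy(p), tolerance = 1e-12)
})

test_that("mean frequency is the power-weighted centroid", {
  expect_equal(mean_frequency(c(1), c(3000)), 3000)
  expect_equal(mean_frequency(c(1, 1), c(2000, 4000)), 3000)
  expect_equal(mean_frequency(c(2, 2), c(2000, 4000)),
               mean_frequency(c(1, 1), c(2000, 4000)))  # scale invariance
  expect_true(is.na(mean_frequency(c(0, 0), c(1, 2))))
  set.seed(7)
  fr <- spectral_frames(0.2 * rnorm(fs), fs, band = c(0, fs / 2))
  mf <- mean(vapply(seq_len(ncol(fr$S)), function(j) {
    as.numeric(mean_frequency(fr$S[, j], fr$freq))
  }, numeric(1)))
  expect_lt(abs(mf - fs / 4) / (fs / 4), 0.05)  # band midpoint
})

test_that("pitch goodness separates harmonic frames from noise and ignores gain", {
  stack <- stack_wave(700)
  fr <- spectral_frames(stack, fs)
  mid <- ncol(fr$S) %/% 2
  pg_stack <- pitch_goodness(fr, mid)
  set.seed(8)
  frn <- spectral_frames(0.25 * rnorm(length(stack)), fs)
  pg_noise <- pitch_goodness(frn, ncol(frn$S) %/% 2)
  expect_gt(pg_stack, pg_noise)
  fr2 <- spectral_frames(stack * 10, fs)
  expect_equal(pitch_goodness(fr2, mid), pg_stack, tolerance = 1e-6)
})

test_that("pitch recovers fundamentals and falls back to mean frequency on noise", {
  fr <- spectral_frames(stack_wave(700), fs)
  mid <- ncol(fr$S) %/% 2
  expect_lt(abs(pitch(fr, mid) - 700), 2)
  sine <- 0.3 * sin(2 * pi * 500 * (0:8819) / fs)
  frs <- spectral_frames(sine, fs)
  expect_lt(abs(pitch(frs, ncol(frs$S) %/% 2) - 500), 2)
  set.seed(9)
  frn <- spectral_frames(0.25 * rnorm(8820), fs)
  j <- ncol(frn$S) %/% 2
  expect_equal(pitch(frn, j),
               as.numeric(mean_frequency(frn$S[, j], frn$freq)))
  # amplitude invariance of the pitch estimate
  fr10 <- spectral_frames(10 * stack_wave(700), fs)
  expect_equal(pitch(fr10, mid), pitch(fr, mid), tolerance = 1e-6)
})

test_that("frequency modulation is ~0 for stationary tones and larger for chirps", {
  tone <- 0.3 * sin(2 * pi * 2000 * (0:8819) / fs)
  frt <- spectral_frames(tone, fs)
  fm_tone <- frequency_modulation(frt, ncol(frt$S) %/% 2)
  expect_lt(fm_tone, 10)
  sweep <- synthesize_syllable(
    syllable_archetype("fm_sweep", f_start = 1000, f_end = 4000,
                       duration_ms = 80), zero_jitter(), fs, 1)$wave
  frc <- spectral_frames(sweep, fs)
  fm_chirp <- frequency_modulation(frc, ncol(frc$S) %/% 2)
  expect_gt(fm_chirp, fm_tone)
  expect_true(fm_chirp >= 0 && fm_chirp <= 90)
  # FM approximately invariant to time reversal
  frr <- spectral_frames(rev(sweep), fs)
  fm_rev <- frequency_modulation(frr, ncol(frr$S) %/% 2)
  expect_lt(abs(fm_rev - fm_chirp), 15)
})

test_that("syllable features are deterministic and recover synthesis truth", {
  w <- stack_wave(700, duration_ms = 100)
  f1 <- syllable_features(w, fs)
  f2 <- syllable_features(w, fs)
  expect_identical(f1, f2)
  expect_lt(abs(f1$duration_ms - 100), 2)
  expect_lt(abs(f1$pitch - 700), 2)
  expect_lt(f1$wiener_entropy, 0)
})

test_that("zero-jitter rendition series have feature CVs at the numerical floor", {
  ses <- synthesize_session(
    study_spec(n_treated_birds = 1, n_vehicle_birds = 1, seed = 31,
               jitter = jitter_model(0, 0, 0, noise_floor_db = -120)),
    1, "UD", "pre", "sixohda")
  ft <- process_session(ses$wave, ses$fs, label_track = ses$labels,
                        meta = list(bird = "t01", treatment = "sixohda",
                                    context = "UD", phase = "pre"))
  for (lab in c("a", "b")) {
    sub <- ft[ft$syllable == lab, ]
    for (col in c("pitch", "mean_frequency", "duration_ms")) {
      v <- sub[[col]]
      expect_lt(sd(v) / abs(mean(v)), 1e-3)
    }
  }
})

test_that("self-similarity is 100/100 for identical renditions and degrades with jitter", {
  a <- stack_wave(700, seed = 1)
  ss <- self_similarity(a, a, fs)
  expect_equal(ss$similarity, 100)
  expect_equal(ss$accuracy, 100)
  set.seed(10)
  noise <- 0.25 * rnorm(length(a))
  cal <- similarity_calibration()
  ss_noise <- self_similarity(a, noise, fs)
  expect_lt(ss_noise$accuracy, 50)  # below the unrelated-sound median
  # monotonicity: smaller feature jitter -> higher mean pairwise accuracy
  arc <- syllable_archetype("harmonic_stack", f0 = 700, duration_ms = 100)
  series_acc <- function(cv) {
    jit <- jitter_model(cv_f0 = cv, cv_duration = 0, cv_amplitude = 0)
    waves <- lapply(1:6, function(i) {
      synthesize_syllable(arc, jit, fs, i)$wave
    })
    series_self_accuracy(waves, fs)$accuracy
  }
  expect_gt(series_acc(0.005), series_acc(0.05))
})
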