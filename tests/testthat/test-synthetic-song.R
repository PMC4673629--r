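test_that("zero-jitter renditions realize the nominal parameters exactly", {
  arc <- syllable_archetype("harmonic_stack", f0 = 700, duration_ms = 100)
  for (seed in 1:5) {
    s <- synthesize_syllable(arc, zero_jitter(), 44100, seed)
    expect_identical(s$realized$f0, 700)
    expect_true(all(is.finite(s$wave)))
  }
})

test_that("realized-f0 jitter CV matches the configured CV (Monte-Carlo)", {
  arc <- syllable_archetype("harmonic_stack", f0 = 700)
  jit <- jitter_model(cv_f0 = 0.02, cv_duration = 0, cv_amplitude = 0)
  f0s <- vapply(1:1000, function(i) {
    synthesize_syllable(arc, jit, 44100, i, render = FALSE)$realized$f0
  }, numeric(1))
  expect_gt(sd(f0s) / mean(f0s), 0.018)
  expect_lt(sd(f0s) / mean(f0s), 0.022)
})

test_that("jitter calibration converges for all jittered parameters", {
  jit <- jitter_model(cv_f0 = 0.015, cv_duration = 0.03, cv_amplitude = 0.05)
  arc <- syllable_archetype("harmonic_stack", f0 = 600, duration_ms = 100)
  r <- lapply(1:1000, function(i) {
    synthesize_syllable(arc, jit, 44100, i, render = FALSE)$realized
  })
  f0 <- vapply(r, `[[`, numeric(1), "f0")
  amp <- vapply(r, `[[`, numeric(1), "amplitude")
  expect_lt(abs(sd(f0) / mean(f0) - 0.015) / 0.015, 0.05)
  expect_lt(abs(sd(amp) / mean(amp) - 0.05) / 0.05, 0.05)
})

test_that("noise bursts are band-limited (out-of-band >= 20 dB down)", {
  arc <- syllable_archetype("noise_burst", band = c(2000, 8000),
                            duration_ms = 100)
  w <- synthesize_syllable(arc, zero_jitter(), 44100, 1)$wave
  p <- Mod(fft(w))^2
  n <- length(w)
  freq <- (seq_len(n) - 1) * 44100 / n
  half <- freq <= 22050
  in_band <- half & freq >= 2200 & freq <= 7800
  out_band <- half & (freq < 1500 | freq > 9000) & freq > 100
  in_db <- 10 * log10(mean(p[in_band]))
  out_db <- 10 * log10(mean(p[out_band]))
  expect_gt(in_db - out_db, 20)
})

test_that("Nyquist violations are rejected", {
  arc <- syllable_archetype("harmonic_stack", f0 = 1500, n_harmonics = 10)
  expect_error(synthesize_syllable(arc, zero_jitter(), fs = 22050, seed = 1),
               "Nyquist")
})

test_that("sessions have one label row per syllable rendition and >= 40 ms gaps", {
  ses <- synthesize_session(tiny_spec(), 1, "UD", "pre", "sixohda",
                            render = FALSE)
  expect_equal(nrow(ses$labels), 3 * 20)
  expect_equal(nrow(ses$truth), 60)
  gaps <- ses$truth$onset[-1] - ses$truth$offset[-60]
  expect_true(all(gaps >= 0.040 - 1e-9))
})

test_that("social context scales truth-table f0 CV by context_cv_ratio", {
  spec <- study_spec(n_treated_birds = 1, n_vehicle_birds = 1,
                     renditions_per_cell = 1000, seed = 7)
  ud <- synthesize_session(spec, 1, "UD", "pre", "sixohda", render = FALSE)
  fd <- synthesize_session(spec, 1, "FD", "pre", "sixohda", render = FALSE)
  cv_of <- function(x) sd(x) / mean(x)
  ratio <- cv_of(fd$truth$f0[fd$truth$syllable == "a"]) /
    cv_of(ud$truth$f0[ud$truth$syllable == "a"])
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.8)
})

test_that("treatment multiplies post-surgery UD CV by treatment_cv_factor", {
  spec <- study_spec(n_treated_birds = 1, n_vehicle_birds = 1,
                     renditions_per_cell = 1000, seed = 9)
  pre <- synthesize_session(spec, 1, "UD", "pre", "sixohda", render = FALSE)
  post <- synthesize_session(spec, 1, "UD", "post", "sixohda", render = FALSE)
  cv_of <- function(x) sd(x) / mean(x)
  ratio <- cv_of(post$truth$f0[post$truth$syllable == "a"]) /
    cv_of(pre$truth$f0[pre$truth$syllable == "a"])
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.8)
  # vehicle birds are untouched
  pre_v <- synthesize_session(spec, 2, "UD", "pre", "vehicle", render = FALSE)
  post_v <- synthesize_session(spec, 2, "UD", "post", "vehicle",
                               render = FALSE)
  ratio_v <- cv_of(post_v$truth$f0[post_v$truth$syllable == "a"]) /
    cv_of(pre_v$truth$f0[pre_v$truth$syllable == "a"])
  expect_gt(ratio_v, 0.85)
  expect_lt(ratio_v, 1.15)
})

test_that("a full study produces one session per bird x context x phase", {
  st <- generate_study(study_spec(seed = 2))
  expect_equal(nrow(st$manifest), (7 + 11) * 2 * 2)
  expect_setequal(unique(st$manifest$treatment), c("sixohda", "vehicle"))
  expect_equal(sum(st$manifest$treatment == "sixohda"), 7 * 4)
})

test_that("identical (spec, seed) reproduce identical truth tables and audio", {
  a <- generate_study(tiny_spec(seed = 12))
  b <- generate_study(tiny_spec(seed = 12))
  expect_identical(a$truth, b$truth)
  expect_identical(a$manifest, b$manifest)
  s1 <- synthesize_session(tiny_spec(seed = 12), 1, "UD", "pre", "sixohda")
  s2 <- synthesize_session(tiny_spec(seed = 12), 1, "UD", "pre", "sixohda")
  expect_identical(s1$wave, s2$wave)
  # truth tables do not depend on whether audio was rendered
  s3 <- synthesize_session(tiny_spec(seed = 12), 1, "UD", "pre", "sixohda",
                           render = FALSE)
  expect_identical(s1$truth, s3$truth)
})

test_that("a null treatment leaves treated and vehicle CVs indistinguishable", {
  ps <- vapply(1:40, function(i) {
    spec <- study_spec(n_treated_birds = 3, n_vehicle_birds = 3,
                       treatment_cv_factor = 1, seed = 1000 + i)
    st <- generate_study(spec)
    cells <- st$truth[st$truth$context == "UD" & st$truth$phase == "post" &
                        st$truth$syllable == "a", ]
    cvs <- tapply(cells$f0, cells$bird, function(x) sd(x) / mean(x))
    trt <- startsWith(names(cvs), "t")
    resampling_unpaired_median_test(cvs[trt], cvs[!trt], n_iter = 400,
                                    seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)   # p roughly uniform under the null
  expect_lt(mean(ps), 0.8)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("WAV and label-track files round-trip through the writers", {
  dir <- withr::local_tempdir()
  ses <- synthesize_session(tiny_spec(seed = 4), 1, "UD", "pre", "sixohda")
  wav_path <- file.path(dir, "s.wav")
  write_wav(ses$wave, ses$fs, wav_path)
  back <- read_wav(wav_path)
  expect_equal(back$fs, 44100)
  expect_lt(max(abs(back$samples - ses$wave)), 1 / 32000)  # 16-bit rounding
  lab_path <- file.path(dir, "s.txt")
  write_label_track(ses$labels, lab_path)
  lab <- read_label_track(lab_path)
  expect_equal(lab$start, ses$labels$start, tolerance = 1e-6)
  expect_equal(lab$label, ses$labels$label)
})

test_that("generate_study refuses to clobber an existing manifest", {
  dir <- withr::local_tempdir()
  generate_study(tiny_spec(seed = 5), out_dir = dir, render = FALSE)
  expect_error(generate_study(tiny_spec(seed = 5), out_dir = dir,
                              render = FALSE), "overwrite")
  expect_silent(generate_study(tiny_spec(seed = 5), out_dir = dir,
                               render = FALSE, overwrite = TRUE))
})
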