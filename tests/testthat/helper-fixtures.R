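# Shared fixture builders (all generated in code at test time).

zero_jitter <- function() jitter_model(cv_f0 = 0, cv_duration = 0,
                                       cv_amplitude = 0)

stack_wave <- function(f0 = 700, duration_ms = 100, fs = 44100, seed = 1,
                       jitter = zero_jitter()) {
  synthesize_syllable(
    syllable_archetype("harmonic_stack", f0 = f0, duration_ms = duration_ms),
    jitter, fs, seed)$wave
}

tiny_spec <- function(seed = 3, ...) {
  study_spec(n_treated_birds = 1, n_vehicle_birds = 1, seed = seed, ...)
}

# two tone bursts with a silent gap, for envelope/segmentation fixtures
two_burst_wave <- function(fs = 44100, burst_ms = 50, gap_ms = 30,
                           amp = 0.3) {
  n <- round(burst_ms * fs / 1000)
  g <- round(gap_ms * fs / 1000)
  burst <- amp * sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  ramp <- round(0.005 * fs)
  env <- rep(1, n)
  env[1:ramp] <- seq(0, 1, length.out = ramp)
  env[(n - ramp + 1):n] <- seq(1, 0, length.out = ramp)
  c(numeric(g), burst * env, numeric(g), burst * env, numeric(g))
}
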