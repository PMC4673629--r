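#' Syllable archetype
#'
#' Describes one syllable type of a bird's motif. Three kinds are supported:
#' `harmonic_stack` (fundamental `f0` plus `n_harmonics` partials with
#' geometric amplitude decay — the low-FM syllable class whose fundamental
#' frequency variability is the classic social-context measure), `fm_sweep`
#' (linear chirp from `f_start` to `f_end`) and `noise_burst` (band-limited
#' noise over `band`).
#'
#' @param kind one of `"harmonic_stack"`, `"fm_sweep"`, `"noise_burst"`.
#' @param f0 fundamental (Hz) for stacks; must lie in [300, 1500] so the
#'   FF-estimation search range covers it.
#' @param f_start,f_end sweep endpoints (Hz).
#' @param band length-2 numeric, noise band (Hz).
#' @param n_harmonics number of partials for stacks (>= 1).
#' @param harmonic_decay amplitude ratio between successive partials.
#' @param duration_ms nominal syllable duration (ms).
#' @param amplitude_db nominal peak amplitude (dB full scale, <= 0).
#' @return object of class `syllable_archetype`.
#' @export
syllable_archetype <- function(kind = c("harmonic_stack", "fm_sweep", "noise_burst"),
                               f0 = 700, f_start = 1000, f_end = 4000,
                               band = c(2000, 8000), n_harmonics = 8,
                               harmonic_decay = 0.75, duration_ms = 100,
                               amplitude_db = -12) {
  kind <- match.arg(kind)
  stopifnot(duration_ms > 0, n_harmonics >= 1, harmonic_decay > 0)
  if (kind == "harmonic_stack" && (f0 < 300 || f0 > 1500)) {
    stop("harmonic stack f0 must lie within [300, 1500] Hz")
  }
  structure(list(kind = kind, f0 = f0, f_start = f_start, f_end = f_end,
                 band = band, n_harmonics = n_harmonics,
                 harmonic_decay = harmonic_decay, duration_ms = duration_ms,
                 amplitude_db = amplitude_db),
            class = "syllable_archetype")
}

#' Rendition-to-rendition jitter model
#'
#' Multiplicative jitter applied independently per rendition. Multipliers are
#' log-normal with unit mean, so a configured CV is realized exactly in the
#' population sense and all jittered parameters stay positive.
#'
#' @param cv_f0 CV of the fundamental-frequency multiplier.
#' @param cv_duration CV of the duration multiplier.
#' @param cv_amplitude CV of the (linear) amplitude multiplier.
#' @param noise_floor_db additive broadband session noise level (dBFS).
#' @return object of class `jitter_model`.
#' @export
jitter_model <- function(cv_f0 = 0.015, cv_duration = 0.03,
                         cv_amplitude = 0.05, noise_floor_db = -70) {
  stopifnot(cv_f0 >= 0, cv_duration >= 0, cv_amplitude >= 0)
  structure(list(cv_f0 = cv_f0, cv_duration = cv_duration,
                 cv_amplitude = cv_amplitude,
                 noise_floor_db = noise_floor_db),
            class = "jitter_model")
}

#' Study design specification
#'
#' Defines a simulated pre/post, two-context song study: `n_treated_birds`
#' receive a variability-reducing treatment whose effect is confined to
#' undirected (UD) song after surgery; female-directed (FD) song is more
#' stereotyped from the start (`context_cv_ratio` < 1 scales all jitter CVs).
#'
#' @param n_treated_birds,n_vehicle_birds group sizes (defaults 7 and 11,
#'   the group sizes of the study design this generator emulates).
#' @param syllables_per_bird motif length (>= 3).
#' @param renditions_per_cell renditions per (bird, context, phase) cell;
#'   the analysis convention uses the first 20.
#' @param context_cv_ratio FD jitter CV = ratio x UD CV, in (0, 1].
#' @param treatment_cv_factor post-surgery UD CVs of treated birds are
#'   multiplied by this factor, in (0, 1].
#' @param jitter baseline UD [jitter_model()].
#' @param fs sampling rate (Hz).
#' @param seed master seed; all per-cell randomness derives from it.
#' @return object of class `study_spec`.
#' @export
study_spec <- function(n_treated_birds = 7, n_vehicle_birds = 11,
                       syllables_per_bird = 3, renditions_per_cell = 20,
                       context_cv_ratio = 0.7, treatment_cv_factor = 0.7,
                       jitter = jitter_model(), fs = 44100, seed = 1) {
  stopifnot(n_treated_birds >= 1, n_vehicle_birds >= 1,
            syllables_per_bird >= 3, renditions_per_cell >= 2,
            context_cv_ratio > 0, context_cv_ratio <= 1,
            treatment_cv_factor > 0, treatment_cv_factor <= 1)
  if (renditions_per_cell < 20) {
    warning("renditions_per_cell < 20: the standard pipeline selects the ",
            "first 20 renditions per cell")
  }
  structure(list(n_treated_birds = n_treated_birds,
                 n_vehicle_birds = n_vehicle_birds,
                 syllables_per_bird = syllables_per_bird,
                 renditions_per_cell = renditions_per_cell,
                 contexts = c("UD", "FD"), phases = c("pre", "post"),
                 context_cv_ratio = context_cv_ratio,
                 treatment_cv_factor = treatment_cv_factor,
                 jitter = jitter, fs = fs, seed = as.integer(seed)),
            class = "study_spec")
}

raised_cosine_env <- function(n, fs, ramp_ms = 5) {
  r <- min(round(ramp_ms * fs / 1000), floor(n / 2))
  env <- rep(1, n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[(n - r + 1):n] <- rev(ramp)
  }
  env
}

band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  # two-sided mask, exact band edges
  keep <- (freq >= band[1] & freq <= band[2]) |
    (freq >= fs - band[2] & freq <= fs - band[1])
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize one syllable rendition
#'
#' Draws per-rendition jitter multipliers, renders the waveform and returns
#' both the audio and the realized (ground-truth) parameters. The amplitude
#' envelope is a raised-cosine ramp (5 ms) at both ends so segmentation local
#' minima exist between syllables.
#'
#' @param archetype a [syllable_archetype()].
#' @param jitter a [jitter_model()].
#' @param fs sampling rate (Hz); must be at least twice the highest
#'   synthesized frequency.
#' @param seed integer seed for this rendition.
#' @param render if `FALSE`, skip waveform rendering and return only the
#'   realized parameters (`wave = NULL`); the parameter draws are identical
#'   either way.
#' @return list with `wave` (numeric or `NULL`), `fs`, and `realized` (list:
#'   `f0` in Hz or `NA` for non-harmonic kinds, `duration_ms`, `amplitude`
#'   linear peak).
#' @export
synthesize_syllable <- function(archetype, jitter = jitter_model(), fs = 44100,
                                seed = 1, render = TRUE) {
  stopifnot(inherits(archetype, "syllable_archetype"),
            inherits(jitter, "jitter_model"))
  f_max <- switch(archetype$kind,
                  harmonic_stack = archetype$f0 * archetype$n_harmonics * 1.1,
                  fm_sweep = max(archetype$f_start, archetype$f_end),
                  noise_burst = archetype$band[2])
  if (fs < 2 * f_max) {
    stop(sprintf("Nyquist violation: fs = %g < 2 x %g Hz", fs, f_max))
  }
  with_seed(seed, {
    dur_ms <- NA_real_
    for (i in 1:10) {  # bounded retries against degenerate duration draws
      dur_ms <- archetype$duration_ms * rlnorm_cv(1, jitter$cv_duration)
      if (dur_ms > 1) break
    }
    if (!(dur_ms > 1)) stop("non-positive syllable duration after jitter")
    m_f0 <- rlnorm_cv(1, jitter$cv_f0)
    m_amp <- rlnorm_cv(1, jitter$cv_amplitude)
    n <- max(round(dur_ms * fs / 1000), 8)
    amp <- db_to_linear(archetype$amplitude_db) * m_amp
    f0_realized <- if (archetype$kind == "harmonic_stack") {
      archetype$f0 * m_f0
    } else {
      NA_real_
    }
    realized <- list(f0 = f0_realized, duration_ms = n / fs * 1000,
                     amplitude = amp)
    if (!render) {
      return(list(wave = NULL, fs = fs, realized = realized))
    }
    t <- (seq_len(n) - 1) / fs
    wave <- switch(
      archetype$kind,
      harmonic_stack = {
        f0 <- archetype$f0 * m_f0
        h <- seq_len(archetype$n_harmonics)
        amps <- archetype$harmonic_decay^(h - 1)
        rowSums(vapply(h, function(k) amps[k] * sin(2 * pi * k * f0 * t),
                       numeric(n)))
      },
      fm_sweep = {
        fa <- archetype$f_start * m_f0
        fb <- archetype$f_end * m_f0
        phase <- 2 * pi * (fa * t + (fb - fa) * t^2 / (2 * max(t)))
        sin(phase)
      },
      noise_burst = band_noise(n, fs, archetype$band)
    )
    wave <- wave / max(abs(wave))
    wave <- wave * amp * raised_cosine_env(n, fs)
    list(wave = wave, fs = fs, realized = realized)
  })
}

# jitter model for one (context, phase, treatment) cell: FD scales all CVs by
# context_cv_ratio; the treatment multiplies post-surgery UD CVs of treated
# birds by treatment_cv_factor.
cell_jitter <- function(spec, context, phase, treatment) {
  j <- spec$jitter
  f <- if (context == "FD") spec$context_cv_ratio else 1
  if (context == "UD" && phase == "post" && treatment == "sixohda") {
    f <- f * spec$treatment_cv_factor
  }
  jitter_model(cv_f0 = j$cv_f0 * f, cv_duration = j$cv_duration * f,
               cv_amplitude = j$cv_amplitude * f,
               noise_floor_db = j$noise_floor_db)
}

# Per-bird motif: one harmonic stack (bird-specific f0), one FM sweep, one
# noise burst, plus extra stacks if syllables_per_bird > 3. Drawn
# deterministically from the master seed.
bird_motif <- function(spec, bird_index) {
  with_seed(derive_seed(spec$seed, 7001L, bird_index), {
    f0 <- stats::runif(1, 500, 900)
    arcs <- list(
      a = syllable_archetype("harmonic_stack", f0 = f0, duration_ms = 100),
      b = syllable_archetype("fm_sweep",
                             f_start = stats::runif(1, 800, 1200),
                             f_end = stats::runif(1, 3500, 5000),
                             duration_ms = 80),
      c = syllable_archetype("noise_burst", band = c(2000, 8000),
                             duration_ms = 60)
    )
    k <- spec$syllables_per_bird
    if (k > 3) {
      for (i in seq_len(k - 3)) {
        arcs[[letters[3 + i]]] <-
          syllable_archetype("harmonic_stack",
                             f0 = stats::runif(1, 400, 1200),
                             duration_ms = stats::runif(1, 70, 120))
      }
    }
    arcs
  })
}

#' Synthesize one recording session
#'
#' Renders `renditions_per_cell` repetitions of a bird's fixed motif with
#' silent inter-syllable gaps, returning the session waveform, an
#' Audacity-style label table and a ground-truth table of realized
#' per-rendition parameters.
#'
#' @param spec a [study_spec()].
#' @param bird_index 1-based bird index within the study.
#' @param context `"UD"` or `"FD"`.
#' @param phase `"pre"` or `"post"`.
#' @param treatment `"vehicle"` or `"sixohda"`.
#' @param render if `FALSE`, skip waveform assembly (truth and labels only).
#' @param gap_ms silent gap between syllables (>= 40 ms).
#' @param motif_gap_ms silent gap between motif renditions.
#' @return list with `wave` (or `NULL`), `fs`, `labels` (start, end, label)
#'   and `truth` (one row per syllable rendition with realized parameters).
#' @export
synthesize_session <- function(spec, bird_index, context, phase, treatment,
                               render = TRUE, gap_ms = 50, motif_gap_ms = 200) {
  stopifnot(inherits(spec, "study_spec"), gap_ms >= 40)
  arcs <- bird_motif(spec, bird_index)
  jit <- cell_jitter(spec, context, phase, treatment)
  ctx_i <- match(context, spec$contexts)
  ph_i <- match(phase, spec$phases)
  fs <- spec$fs
  n_syl <- length(arcs)
  n_total <- spec$renditions_per_cell * n_syl
  pieces <- vector("list", n_total)
  onset_v <- offset_v <- f0_v <- dur_v <- amp_v <- numeric(n_total)
  syl_v <- kind_v <- character(n_total)
  rend_v <- integer(n_total)
  t_cursor <- motif_gap_ms / 1000
  idx <- 0L
  for (r in seq_len(spec$renditions_per_cell)) {
    for (s in seq_len(n_syl)) {
      idx <- idx + 1L
      seed <- derive_seed(spec$seed, bird_index, ctx_i, ph_i, s, r)
      syl <- synthesize_syllable(arcs[[s]], jit, fs, seed, render = render)
      onset_v[idx] <- t_cursor
      offset_v[idx] <- t_cursor + syl$realized$duration_ms / 1000
      f0_v[idx] <- syl$realized$f0
      dur_v[idx] <- syl$realized$duration_ms
      amp_v[idx] <- syl$realized$amplitude
      syl_v[idx] <- names(arcs)[s]
      kind_v[idx] <- arcs[[s]]$kind
      rend_v[idx] <- r
      if (render) pieces[[idx]] <- list(start = t_cursor, wave = syl$wave)
      gap <- if (s == n_syl) motif_gap_ms else gap_ms
      t_cursor <- offset_v[idx] + gap / 1000
    }
  }
  truth <- data.frame(
    bird = bird_id(spec, bird_index), treatment = treatment,
    context = context, phase = phase, syllable = syl_v, rendition = rend_v,
    onset = onset_v, offset = offset_v, f0 = f0_v, duration_ms = dur_v,
    amplitude = amp_v, kind = kind_v, stringsAsFactors = FALSE)
  wave <- NULL
  if (render) {
    n_total <- ceiling((t_cursor + motif_gap_ms / 1000) * fs)
    wave <- with_seed(derive_seed(spec$seed, bird_index, ctx_i, ph_i, 9999L), {
      stats::rnorm(n_total, sd = db_to_linear(jit$noise_floor_db))
    })
    for (p in pieces) {
      i0 <- round(p$start * fs) + 1
      wave[i0:(i0 + length(p$wave) - 1)] <-
        wave[i0:(i0 + length(p$wave) - 1)] + p$wave
    }
  }
  labels <- data.frame(start = truth$onset, end = truth$offset,
                       label = truth$syllable, stringsAsFactors = FALSE)
  list(wave = wave, fs = fs, labels = labels, truth = truth)
}

bird_id <- function(spec, i) {
  if (i <= spec$n_treated_birds) sprintf("t%02d", i)
  else sprintf("v%02d", i - spec$n_treated_birds)
}

bird_treatment <- function(spec, i) {
  if (i <= spec$n_treated_birds) "sixohda" else "vehicle"
}

#' Generate a full simulated study
#'
#' One session per (bird x context x phase). Ground-truth tables are always
#' produced; audio and label files are written only when `out_dir` is given
#' and `render = TRUE`. The whole dataset is reproducible from
#' `(spec, spec$seed)`.
#'
#' @param spec a [study_spec()].
#' @param out_dir optional output directory for WAV + label + table files.
#' @param render render and write audio (requires `out_dir`).
#' @param overwrite allow overwriting an existing manifest in `out_dir`.
#' @return list with `truth` (all sessions row-bound), `manifest` (one row
#'   per session: bird, treatment, context, phase, seed, file paths) and
#'   `spec`.
#' @export
generate_study <- function(spec, out_dir = NULL, render = !is.null(out_dir),
                           overwrite = FALSE) {
  stopifnot(inherits(spec, "study_spec"))
  if (render && is.null(out_dir)) stop("render = TRUE requires out_dir")
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.tsv")
    if (file.exists(manifest_path) && !overwrite) {
      stop("manifest already exists in ", out_dir, "; use overwrite = TRUE")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  n_birds <- spec$n_treated_birds + spec$n_vehicle_birds
  truth_all <- list()
  man <- list()
  k <- 0L
  for (b in seq_len(n_birds)) {
    for (context in spec$contexts) {
      for (phase in spec$phases) {
        k <- k + 1L
        trt <- bird_treatment(spec, b)
        ses <- synthesize_session(spec, b, context, phase, trt,
                                  render = render)
        stem <- sprintf("%s_%s_%s", bird_id(spec, b), context, phase)
        wav_file <- lab_file <- NA_character_
        if (!is.null(out_dir) && render) {
          wav_file <- file.path(out_dir, paste0(stem, ".wav"))
          lab_file <- file.path(out_dir, paste0(stem, "_labels.txt"))
          write_wav(ses$wave, ses$fs, wav_file)
          write_label_track(ses$labels, lab_file)
        }
        truth_all[[k]] <- ses$truth
        man[[k]] <- data.frame(
          session = stem, bird = bird_id(spec, b), treatment = trt,
          context = context, phase = phase,
          seed = derive_seed(spec$seed, b, match(context, spec$contexts),
                             match(phase, spec$phases)),
          wav = wav_file, labels = lab_file, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth_all)
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(truth = truth, manifest = manifest, spec = spec)
}
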