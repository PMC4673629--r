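# songvar

Quantifying rendition-to-rendition vocal variability in zebra finch song,
and attributing changes in that variability to an experimental treatment.

Adult male zebra finches sing a fixed motif whose syllables vary subtly from
rendition to rendition. The variability is socially regulated — undirected
(UD) song is more variable than female-directed (FD) song — and is
controlled by dopamine in Area X, the song-dedicated basal ganglia nucleus.
Studies that deplete Area X dopamine (e.g. with 6-OHDA) ask: did UD or FD
variability change, and was the change caused by the treatment rather than
by surgery or time? `songvar` implements the complete measurement and
inference chain for that question, for researchers in birdsong
neuroscience and computational bioacoustics.

## What it computes

* **Synthetic song studies** — zebra-finch-like sessions (harmonic stacks,
  FM sweeps, noise bursts) with log-normal rendition jitter whose CV is
  controlled exactly, a UD > FD context structure (`context_cv_ratio`), and
  a treatment that multiplies post-surgery UD jitter CVs of treated birds
  by `treatment_cv_factor`. Ground-truth tables make every downstream stage
  testable.
* **Segmentation** — short-time RMS envelope (dBFS), syllables as
  supra-threshold runs split at local minima, Audacity label-track I/O,
  first-20-renditions selection per syllable type.
* **Acoustic features** — two-taper DPSS multitaper front end; per-syllable
  duration, pitch, pitch goodness (cepstral peak), Wiener entropy
  (log geometric/arithmetic spectral mean), frequency modulation, mean
  frequency, amplitude; DTW-based rendition self-similarity/accuracy
  percentages.
* **FF variability** — autocorrelation fundamental-frequency estimates of
  harmonic stacks (parabolic interpolation, quality gating) and their
  rendition CV: `CV = sd(FF)/mean(FF)`.
* **Resampling statistics** — sign-flip paired test, label-permutation
  unpaired median test, permutation one-way ANOVA, Mann–Whitney U
  confirmation, bootstrap power; add-one-corrected p-values, fully seeded.
* **Effect sizes and verdicts** — the bounded contrast
  `(A − B)/(A + B)` per syllable and feature, across-group comparisons,
  and the decision rule: a measure shows a *treatment effect* when the
  treated group's pre/post p < α and the vehicle group's is not.
* **Densitometry** — immunoblot background correction, per-lane GAPDH
  normalization, group comparison, and the TH fiber-loss percentage
  `100 × (1 − treated/vehicle)`.

## Worked example

Simulate a study at the default design (7 treated vs 11 vehicle birds, UD
and FD contexts, pre/post phases, 20 renditions per cell, treatment factor
0.7 applied to UD only), analyze the ground-truth feature tables, and read
off the verdicts:

```r
library(songvar)

spec  <- study_spec(seed = 11)
study <- generate_study(spec)
fit   <- analyze_study(study$truth, features = c("f0", "duration_ms", "amplitude"),
                       n_iter = 2000, seed = 11)
summary(fit)
```

```
Treatment-attribution summary
  UD: 3/6 measures with a treatment effect (f0/cv, duration_ms/cv, amplitude/cv)
  FD: 0/6 measures with a treatment effect
Across-group effect-size tests (unpaired median):
 context     feature measure median_effect_treated median_effect_vehicle p_across_groups
      UD          f0      cv         -8.347545e-02         -3.032926e-02    0.2008995502
      UD duration_ms      cv         -2.646787e-01         -3.780175e-03    0.0004997501
      UD   amplitude      cv         -1.821176e-01          2.196354e-02    0.0009995002
      ...
```

The variability (CV) measures come back `treatment_effect` in UD and
`no_effect` in FD — the implanted pattern: variability fell only where the
simulated dopamine depletion acted. The negative treated effect-size
medians (post minus pre over post plus pre) say the same thing on a −1 to 1
scale. Mean-level measures stay at `no_effect` because the treatment
changes variability, not feature means.

The same analysis runs from rendered audio instead of truth tables:

```r
run_study_pipeline(list(spec = study_spec(n_treated_birds = 2, n_vehicle_birds = 2, seed = 1),
                        render_audio = TRUE, out_dir = "scratch/demo"))
```

which synthesizes WAV sessions, segments them by envelope minima, extracts
features and FF per rendition, and writes `features.tsv`, `verdicts.tsv`
and `report.tsv`. A thin command-line wrapper with `simulate`, `segment`,
`features`, `ffcv`, `analyze`, `blots` and `report` subcommands is at
`inst/scripts/songvar-pipeline.R`.

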