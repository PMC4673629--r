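---
title: "Measuring vocal variability in zebra finch song: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal variability in zebra finch song: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songvar)
```

## The scientific problem

Adult male zebra finches sing a stereotyped motif — a fixed sequence of
syllables — but the acoustic details of each syllable vary from rendition to
rendition. That variability is behaviorally regulated: song directed at a
female (FD) is more stereotyped than song produced alone (undirected, UD),
and the difference is under dopaminergic control in Area X, the song-dedicated
basal ganglia nucleus. Experiments that deplete dopamine in Area X (for
example with 6-OHDA) ask whether rendition-to-rendition variability changes,
in which social context, and whether the change can be attributed to the
treatment rather than to surgery or time.

`songvar` implements that full analysis chain: a synthetic song generator
with controllable variability structure, amplitude-envelope syllable
segmentation, SAP-style acoustic features with rendition self-similarity,
fundamental-frequency (FF) variability for harmonic stacks, resampling
statistics, bounded effect sizes, a treatment-attribution decision rule, and
immunoblot densitometry for the accompanying dopamine biomarkers.

## The synthetic song generator

No public corpus pairs pre/post-treatment recordings with ground truth, so
the generator is a first-class module: every downstream stage is validated
against parameters the generator is known to have implanted.

A bird's motif is a fixed sequence of at least three syllable archetypes —
a harmonic stack (fundamental `f0` with geometrically decaying partials),
a linear FM sweep, and a band-limited noise burst — repeated once per motif
rendition with silent gaps of at least 40 ms. The motif never drops or
reorders syllables: keeping sequence fixed isolates acoustic variability,
which is the quantity under study.

Rendition-to-rendition jitter is multiplicative and log-normal. A
multiplier with unit mean and coefficient of variation (CV) `c` is drawn
independently per rendition for fundamental frequency, duration, and
amplitude. Log-normal draws guarantee positivity and give exact CV control:
`sdlog = sqrt(log(1 + c^2))`, `meanlog = -sdlog^2/2`. Sample CVs converge to
the configured values (relative error below 5% at 1000 renditions; the test
suite checks this).

The study design mirrors a two-group pre/post experiment: 7 treated and 11
vehicle birds by default, two contexts (UD, FD), two phases (pre, post), 20
renditions per cell. Two structural parameters carry the science:

* `context_cv_ratio` (default 0.7): FD jitter CVs are this fraction of UD
  CVs, implanting the UD > FD variability ordering.
* `treatment_cv_factor` (default 0.7): post-surgery UD jitter CVs of treated
  birds are multiplied by this factor; FD cells and vehicle birds are
  untouched. This is the simulated dopamine-depletion effect — a
  multiplicative reduction of UD variability only.

Default magnitudes (UD `cv_f0` = 0.015, duration CV 0.03, amplitude CV
0.05) are configurable choices in the range reported for adult zebra finch
harmonic stacks and syllable timing, not measured ground truth; no public
per-bird values exist to calibrate against. The raised-cosine 5 ms
onset/offset ramps guarantee that the amplitude envelope has unambiguous
local minima between syllables, which is what the segmenter keys on.
Everything derives deterministically from one master seed via a
per-(bird, context, phase, syllable, rendition) seed hash, so identical
specifications reproduce identical audio and truth tables, whether or not
audio is rendered.

What the generator deliberately does not model: syringeal production
physics, song-learning dynamics, motif syntax variation, cage noise,
reverberation, or overlapping calls. Passing tests on this corpus therefore
demonstrate that the measurement chain is correct and well calibrated, not
that it is robust to every artifact of real recordings; the label-track
input path exists so hand-segmented real data can enter the same pipeline.

## Segmentation

The envelope is short-time RMS in 1 ms hops with a 2 ms window, in dBFS —
standard practice for birdsong, fast, and threshold-interpretable. Syllables
are maximal supra-threshold runs (default threshold −45 dBFS), with dips
shorter than 5 ms merged and runs shorter than 10 ms discarded; zebra finch
syllables are rarely shorter than 10 ms and inter-syllable gaps rarely
shorter than 5 ms. Intervals are half-open, in seconds, with 0-based sample
indexing. When a label track is supplied its times are authoritative over
detected boundaries, and overlap-maximizing assignment (ties to the earlier
label) maps segments to syllable types; labels starting with "i" mark
introductory notes and are excluded. Analysis uses the first 20 renditions
of each syllable type by onset time — adding renditions beyond 20 yields no
appreciable gain in test power, and a fixed count keeps cells comparable.
Cells with fewer than 20 renditions are excluded with a warning. Consecutive
renditions are selected purely by onset order; whether interrupting calls
should reset "consecutive" is ambiguous in field practice, and we do not
attempt it.

## Acoustic features

The front end is a two-taper DPSS (Slepian) multitaper spectrogram with a
9.27 ms window (409 samples at 44.1 kHz) advanced ~1.36 ms per frame, the
analysis band 430 Hz to Nyquist — the SAP-style configuration. Tapers come
from the symmetric tridiagonal eigenproblem, computed in base R and
memoized. Note the design bandwidth: NW/N × fs ≈ 160 Hz, so single-frame
peak positions are only localized to that scale.

Per frame:

* **Wiener entropy** — `log(geometric mean / arithmetic mean)` of band
  power; exactly 0 on a flat spectrum, strongly negative on tonal sounds,
  invariant to gain. Stored signed; reported as magnitude in summary tables
  (the conventional display, which also satisfies the non-negativity
  requirement of the effect-size formula).
* **Pitch goodness** — height of the real-cepstrum peak over quefrencies
  corresponding to 300–1500 Hz fundamentals; gain-invariant because the log
  spectrum shifts only its zeroth quefrency under scaling.
* **Pitch** — autocorrelation (via the Wiener–Khinchin theorem on the
  zero-padded frame power spectrum, debiased by the tapers' own lag window)
  peak in the 300–1500 Hz lag band, refined by parabolic interpolation. A
  frame counts as periodic when pitch goodness clears a harmonicity
  threshold *or* the normalized autocorrelation peak exceeds 0.3 — the
  second clause covers pure tones, whose cepstral peak is weak although the
  period is unambiguous. Non-periodic frames fall back to mean frequency.
  The harmonicity threshold is the 90th percentile of pitch goodness on
  white-noise frames from a seeded calibration corpus, since no published
  constant exists for this gate.
* **Frequency modulation** — `atan(|dS/dt| / |dS/df|)` in degrees over the
  frame's peak bins, with the derivative spectra computed as central finite
  differences on the spectrogram grid (per hop, per bin). A stationary tone
  gives ≈0°, fast sweeps give large angles, and the grid normalization
  yields values in the 30–50° range typical of song syllables.
* **Mean frequency** — the power-weighted spectral centroid over the band.

Per syllable, spectral features are aggregated as power-weighted means over
frames (suppressing onset/offset ramp artifacts); duration comes from the
segment bounds. The aggregation rule is our choice — published feature
tables do not print one.

**Self-similarity and accuracy.** Two renditions are compared frame-by-frame
in the scaled space of (pitch, FM, Wiener entropy, pitch goodness). Frame
distances convert to percentages against an empirical calibration
distribution of distances between frames of unrelated synthetic sounds
(regenerated per session from a fixed seed — a documented dialect
difference from GUI-era tools whose calibration tables were never
published). Accuracy is the mean frame similarity along the best monotone
(DTW) alignment; similarity is the fraction of reference frames whose best
local-neighborhood match exceeds 50%. Identical renditions score exactly
100/100; series accuracy decreases monotonically with injected jitter —
the property the downstream stereotypy analyses rely on. Series-level
scores average consecutive rendition pairs (rendition r as reference for
r+1); all-versus-first is a configurable alternative.

## Fundamental-frequency variability

For harmonic stacks (operationally: mean FM < 15° and pitch goodness above
the harmonicity threshold), FF is estimated from a single 16 ms window at
the syllable midpoint — the midpoint because no standard window placement is
published — by normalized time-domain autocorrelation, peak in the
300–1500 Hz lag band, parabolic interpolation. The peak height is a quality
score; measurements below 0.3 are excluded as invalid (white noise never
passes). The estimator is unbiased to within 2 Hz on noiseless stacks at
400–1300 Hz. FF variability per cell is the sample (n−1) CV over valid
renditions — (n−1) because n = 20 is small. The CV is transposition
invariant.

At 20 renditions the CV estimate itself carries sampling noise of roughly
`1/sqrt(2(n-1))` ≈ 16% relative, so a true FD/UD ratio of 0.7 shows the
expected ordering in ~93% of simulated birds, not ~100%; tests assert at
that achievable level.

## Resampling statistics

All tests simulate the null by resampling, with the add-one
(Davison–Hinkley) correction `p = (1 + #{null ≥ obs}) / (1 + n_iter)`, so p
is never 0 and 10,000 iterations give stable three-decimal p-values.

* **Paired test** — statistic `mean(post − pre)`; null by independent sign
  flips of each pair's difference; two-sided by absolute exceedance.
* **Unpaired median test** — statistic `median(a) − median(b)`; null by
  permuting group labels over the pooled sample; two-sided. A
  mean-difference statistic is available as an option because both dialects
  appear in field reports.
* **One-way ANOVA** — the F-form between/within variance ratio; null by
  permuting observations across groups; one-sided by construction. This is
  the test that justifies treating syllables as independent units: distinct
  implanted syllable means give a significant within-bird syllable effect.
* **Mann–Whitney U** — the confirmation test; delegated to
  `stats::wilcox.test` (exact for small groups, normal approximation with
  tie handling otherwise).

Sign-flip and label-permutation nulls are the standard constructions for
these designs. Each test matches exhaustive enumeration (2^8 sign patterns;
C(8,4) label splits) within binomial Monte-Carlo error, and both calibrate
to nominal type-I error within ±1.5 percentage points at α = 0.05 under
Gaussian nulls. One degenerate case is worth knowing: with tied data such
as groups {0,0} and {10,10}, the exhaustive permutation null reproduces the
separation in 2 of 6 label splits, so the exact p is 1/3 — a faithful
permutation test cannot report a smaller value there.

**Power** is estimated by case-resampling bootstrap (resampling the
observed data with replacement, preserving pairing or grouping, and
counting rejections), labeled "bootstrap power" in output because the
field's power procedure for these tables is not printed anywhere. Near the
null this estimator is upward-biased at small n — the bootstrap recenters
on the observed rather than the true effect — so "power ≈ α under the
null" holds only loosely; the tests document and allow that bias.

## Effect sizes and the decision rule

The bounded effect size `(A − B)/(A + B)` places every feature on a −1 to 1
scale: antisymmetric, scale-invariant (so between-syllable magnitude
differences cannot dominate), zero at equality. For surgery comparisons
A = post and B = pre; for social-context comparisons A = FD and B = UD; the
sign conventions are recorded with each value. For variability comparisons
A and B are rendition CVs; for level comparisons, rendition means. Wiener
entropy enters as a magnitude so both arguments are non-negative. When a
cell's CV is exactly zero in both conditions the effect is undefined
(0/0) and flagged rather than silently zeroed.

Two complementary views are computed, because they answer different
questions and can disagree: (i) within-group resampling paired tests on raw
per-syllable values pre versus post (one per treatment group), and (ii)
across-group unpaired median tests on per-syllable effect sizes (treated
versus vehicle). The decision rule operates on view (i): a measure is
attributed to the treatment when the treated group's p < α *and* the
vehicle group's p ≥ α. The verdict taxonomy makes the remaining cases
explicit — `both_changed` (both groups significant: a surgery or time
confound) and `no_effect` — rather than conflating them.

Under the global null each feature yields a false `treatment_effect` at
rate ≈ α(1−α) ≈ 0.0475 (treated significant and vehicle not,
independently); the acceptance suite measures this. With the default
implanted effect (factor 0.7 in UD only), studies at 7-vs-11-bird scale
return `treatment_effect` for the UD variability measures defined on all
syllables (duration CV, amplitude CV: 21 treated syllable pairs each) and
`no_effect` for FD in well over 80% of replicates. FF CV is analyzed the
same way but with only one harmonic stack per bird (7 treated pairs) its
power is materially lower — the same low-n caveat that applies to real
harmonic-stack inventories unless birds are bred for multiple stacks.

## Densitometry

Immunoblot quantification is arithmetic, and implemented as such: corrected
volume = raw − same-size background (negative values clipped to zero and
flagged, because background exceeding signal indicates a measurement
problem); normalized signal = corrected target / corrected GAPDH per lane
(undefined when the loading control is zero; the lane is excluded). Group
comparison uses the unpaired resampling test on the mean difference
(median available) confirmed by Mann–Whitney U; at n = 4 per group, exact
enumeration gives a floor of p = 2/70 ≈ 0.029 for complete separation —
the low-n regime these experiments operate in, which the tests document.
The immunohistochemistry fiber-loss measure is
`100 × (1 − treated/vehicle)` on mean ROI intensities. Band ROI drawing
from gel images is out of scope; inputs are measured volume tables.

## Numerical choices and problem sizes

Defaults: fs 44.1 kHz; FFT length 1024 (padded to ≥ 2× window for clean
autocorrelation); envelope floor −120 dB; resampling 10,000 iterations for
reported p-values (reduced to 800–2000 in simulation loops, where only
rejection at α = 0.05 matters); verdict-rate properties use 50 effect
replicates and 150 null replicates at the 7-vs-11-bird design; type-I
calibration uses 1000 outer simulations × 2000 resamples. These sizes give
Monte-Carlo error comfortably smaller than the property bands they are
checked against while keeping a full run of the suite on one CPU
reasonable.

Tie-breaks and degenerate inputs: exact overlap ties in label assignment go
to the earlier label; all-zero paired differences give p = 1; identical
constant groups give p = 1; all-zero spectra flag entropy/centroid as NA;
sub-window segments are zero-padded and flagged; FF series with fewer than
2 valid measurements are undefined.

## Known limitations

* Synthetic song is spectrally simple; robustness to cage noise, overlap,
  and recording-chain variation is untested by design.
* The similarity calibration is corpus-relative; absolute
  similarity/accuracy percentages are comparable within a `songvar`
  analysis but not numerically interchangeable with GUI-era tools.
* Bootstrap power is a labeled approximation, biased upward near the null
  at small n.
* No multiple-testing correction is applied across features, matching the
  analysis convention this package mirrors; users scanning many features
  should apply their own correction.
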