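Package: songvar
Title: Vocal Variability Analysis for Zebra Finch Song Under Dopamine Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rendition-to-rendition vocal variability in
    zebra finch song and attributing changes to an experimental treatment.
    Includes a synthetic song generator (harmonic stacks, frequency sweeps and
    noise syllables with controllable jitter, social-context structure and a
    simulated dopamine-depletion effect), amplitude-envelope syllable
    segmentation, SAP-style acoustic features (pitch, pitch goodness, Wiener
    entropy, frequency modulation, mean frequency) with rendition
    self-similarity scoring, autocorrelation-based fundamental-frequency
    estimation and its coefficient of variation, resampling statistics
    (sign-flip paired test, permutation unpaired-median test, permutation
    one-way ANOVA, bootstrap power), bounded effect sizes (A-B)/(A+B) with a
    treatment-attribution decision rule, and immunoblot densitometry
    normalization with group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
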