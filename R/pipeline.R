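# Pipeline orchestration: session processing from audio, and the
# simulate -> segment -> features -> analyze -> report arc.

#' Extract per-rendition features from one session recording
#'
#' Runs envelope segmentation, label assignment (label track when supplied,
#' authoritative over detected boundaries; otherwise a motif template),
#' first-n rendition selection per syllable type, and per-syllable feature
#' extraction including the FF measurement.
#'
#' @param wave session waveform.
#' @param fs sampling rate (Hz).
#' @param label_track optional data.frame (`start`, `end`, `label`).
#' @param template optional motif template (character vector).
#' @param meta named list of metadata columns to attach (bird, treatment,
#'   context, phase, ...).
#' @param n renditions per syllable type to keep.
#' @param threshold_db,min_dur_ms,min_gap_ms segmentation parameters.
#' @return data.frame, one row per selected rendition, with segment bounds,
#'   acoustic features and `ff`, `ff_quality`, `ff_valid` columns.
#' @export
process_session <- function(wave, fs, label_track = NULL, template = NULL,
                            meta = list(), n = 20, threshold_db = -45,
                            min_dur_ms = 10, min_gap_ms = 5) {
  env <- amplitude_envelope(wave, fs)
  segs <- segment_syllables(env, threshold_db, min_dur_ms, min_gap_ms)
  if (nrow(segs) == 0) return(NULL)
  segs <- assign_labels(segs, label_track = label_track, template = template)
  if (!is.null(label_track)) {
    # label-track times are authoritative over detected boundaries
    for (i in seq_len(nrow(segs))) {
      if (segs$excluded[i]) next
      ov <- pmin(segs$offset[i], label_track$end) -
        pmax(segs$onset[i], label_track$start)
      j <- which.max(ov)
      segs$onset[i] <- label_track$start[j]
      segs$offset[i] <- label_track$end[j]
    }
  }
  segs <- segs[!segs$excluded, , drop = FALSE]
  rows <- list()
  for (lab in unique(segs$label)) {
    cell <- segs[segs$label == lab, , drop = FALSE]
    cell <- select_renditions(cell, n)
    if (is.null(cell)) next
    for (r in seq_len(nrow(cell))) {
      i0 <- max(round(cell$onset[r] * fs) + 1, 1)
      i1 <- min(round(cell$offset[r] * fs), length(wave))
      slice <- wave[i0:i1]
      feats <- syllable_features(slice, fs)
      ffm <- estimate_ff(slice, fs)
      row <- data.frame(syllable = lab, rendition = r,
                        onset = cell$onset[r], offset = cell$offset[r],
                        stringsAsFactors = FALSE)
      row <- cbind(row, feats,
                   data.frame(ff = ffm$ff, ff_quality = ffm$quality,
                              ff_valid = ffm$valid))
      for (mn in names(meta)) row[[mn]] <- meta[[mn]]
      rows[[length(rows) + 1]] <- row
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the full study pipeline
#'
#' Orchestrates simulate -> (segment -> features | truth features) ->
#' analyze -> report with deterministic per-stage seeds derived from the
#' master seed. With `render_audio = TRUE` every session is synthesized,
#' segmented and measured from audio; otherwise the generator's ground-truth
#' tables (realized per-rendition parameters) feed the analysis directly.
#'
#' @param config list with elements `spec` (a [study_spec()]; or arguments
#'   for one), optional `out_dir`, `render_audio` (default FALSE), `n_iter`
#'   (default 2000), `alpha` (default 0.05), `features` (default the truth
#'   features `f0`, `duration_ms`, `amplitude`), `report` (default TRUE).
#' @param quiet suppress stage logging.
#' @return list with `study`, `feature_table`, `analysis` (a
#'   `song_study_analysis`), `report` (data.frame or NULL) and `config`.
#' @export
run_study_pipeline <- function(config = list(), quiet = FALSE) {
  spec <- config$spec %||% study_spec()
  n_iter <- config$n_iter %||% 2000
  alpha <- config$alpha %||% 0.05
  render <- isTRUE(config$render_audio)
  features <- config$features %||% c("f0", "duration_ms", "amplitude")
  log_stage <- function(...) if (!quiet) message("[songvar] ", sprintf(...))
  log_stage("simulate: %d birds x {%s} x {%s}, %d renditions/cell, seed %d",
            spec$n_treated_birds + spec$n_vehicle_birds,
            paste(spec$contexts, collapse = ","),
            paste(spec$phases, collapse = ","),
            spec$renditions_per_cell, spec$seed)
  study <- generate_study(spec, out_dir = config$out_dir,
                          render = render && !is.null(config$out_dir),
                          overwrite = isTRUE(config$overwrite))
  if (render) {
    log_stage("segment + features: processing %d sessions from audio",
              nrow(study$manifest))
    tabs <- lapply(seq_len(nrow(study$manifest)), function(k) {
      m <- study$manifest[k, ]
      b <- which(vapply(seq_len(spec$n_treated_birds + spec$n_vehicle_birds),
                        function(i) bird_id(spec, i) == m$bird, logical(1)))
      ses <- synthesize_session(spec, b, m$context, m$phase, m$treatment)
      process_session(ses$wave, ses$fs, label_track = ses$labels,
                      meta = list(bird = m$bird, treatment = m$treatment,
                                  context = m$context, phase = m$phase),
                      n = min(spec$renditions_per_cell, 20))
    })
    feature_table <- do.call(rbind, tabs)
    features <- config$features %||%
      c("ff", "duration_ms", "mean_frequency", "wiener_entropy",
        "frequency_modulation", "pitch_goodness")
    if ("ff" %in% features) {
      feature_table$ff[!feature_table$ff_valid] <- NA_real_
    }
  } else {
    log_stage("features: using generator truth tables (%d renditions)",
              nrow(study$truth))
    feature_table <- study$truth
  }
  log_stage("analyze: %d resampling iterations, alpha = %g", n_iter, alpha)
  analysis <- analyze_study(feature_table, features = features,
                            n_iter = n_iter, seed = spec$seed, alpha = alpha)
  rep <- NULL
  if (config$report %||% TRUE) {
    log_stage("report: summary table")
    rep <- build_report(feature_table, features = features, n_iter = n_iter,
                        seed = derive_seed(spec$seed, 4242L),
                        power_outer = config$power_outer %||% 100)
  }
  if (!is.null(config$out_dir)) {
    utils::write.table(feature_table,
                       file.path(config$out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(analysis$verdicts,
                       file.path(config$out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rep)) {
      utils::write.table(rep, file.path(config$out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(study = study, feature_table = feature_table, analysis = analysis,
       report = rep, config = config)
}
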