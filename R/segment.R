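#' Amplitude envelope in dB full scale
#'
#' Short-time RMS of the signal in `hop_ms` steps with a `window_ms` window,
#' expressed in dBFS. Scaling the audio by a factor g shifts the whole
#' envelope by 20*log10(g) (down to the -120 dB floor).
#'
#' @param wave numeric waveform.
#' @param fs sampling rate (Hz).
#' @param window_ms analysis window (ms), must be >= `hop_ms`.
#' @param hop_ms hop (ms), > 0.
#' @return list with `db` (envelope, one value per hop), `t` (frame start
#'   times, s), `hop_s` and `fs`.
#' @export
amplitude_envelope <- function(wave, fs, window_ms = 2, hop_ms = 1) {
  if (length(wave) == 0) stop("empty waveform")
  stopifnot(window_ms >= hop_ms, hop_ms > 0)
  w <- max(round(window_ms * fs / 1000), 1)
  h <- max(round(hop_ms * fs / 1000), 1)
  n <- length(wave)
  n_frames <- ceiling(n / h)
  cs <- c(0, cumsum(wave^2))
  starts <- (seq_len(n_frames) - 1) * h + 1
  ends <- pmin(starts + w - 1, n)
  ms <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  list(db = 10 * log10(pmax(ms, 1e-12)), t = (starts - 1) / fs,
       hop_s = h / fs, fs = fs)
}

#' Segment syllables from an amplitude envelope
#'
#' Syllables are maximal supra-threshold runs of the envelope; dips below
#' threshold (the local minima between sounds) split them. Gaps shorter than
#' `min_gap_ms` are merged and runs shorter than `min_dur_ms` discarded.
#' Intervals are half-open `[onset, offset)` in seconds, sorted and
#' non-overlapping.
#'
#' @param env result of [amplitude_envelope()].
#' @param threshold_db segmentation threshold (dBFS), above the noise floor.
#' @param min_dur_ms minimum syllable duration (ms).
#' @param min_gap_ms minimum silent gap (ms); shorter dips are merged.
#' @return data.frame with columns `onset`, `offset` (s); zero rows when no
#'   sound exceeds the threshold.
#' @export
segment_syllables <- function(env, threshold_db = -45, min_dur_ms = 10,
                              min_gap_ms = 5) {
  above <- env$db > threshold_db
  if (!any(above)) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(onset = env$t[starts[r$values]],
                    offset = env$t[ends[r$values]] + env$hop_s)
  # merge sub-min_gap dips
  if (nrow(seg) > 1) {
    keep <- list(seg[1, ])
    for (i in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      if ((seg$onset[i] - last$offset) * 1000 < min_gap_ms) {
        keep[[length(keep)]]$offset <- seg$offset[i]
      } else {
        keep[[length(keep) + 1]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }
  seg <- seg[(seg$offset - seg$onset) * 1000 >= min_dur_ms, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Assign syllable labels to detected segments
#'
#' With a label track, each segment takes the label of maximal temporal
#' overlap (ties broken by the earlier label; zero overlap marks the segment
#' excluded). With a motif `template` (character vector of labels, e.g.
#' `c("a","b","c")`), labels are assigned cyclically in onset order.
#' Labels found in `exclude` (or starting with "i", the introductory-note
#' convention) are marked excluded from analysis.
#'
#' @param segments data.frame from [segment_syllables()].
#' @param label_track optional data.frame (`start`, `end`, `label`).
#' @param template optional character vector of motif labels.
#' @param exclude labels treated as introductory notes / calls.
#' @return `segments` with added `label` and `excluded` columns.
#' @export
assign_labels <- function(segments, label_track = NULL, template = NULL,
                          exclude = c("i", "call")) {
  if (is.null(label_track) && is.null(template)) {
    stop("supply either a label_track or a motif template")
  }
  n <- nrow(segments)
  lab <- character(n)
  if (!is.null(label_track)) {
    for (i in seq_len(n)) {
      ov <- pmin(segments$offset[i], label_track$end) -
        pmax(segments$onset[i], label_track$start)
      ov[ov < 0] <- 0
      if (all(ov == 0)) {
        lab[i] <- NA_character_
      } else {
        lab[i] <- label_track$label[which.max(ov)]  # which.max = earlier on tie
      }
    }
  } else {
    ord <- order(segments$onset)
    lab[ord] <- rep_len(template, n)
  }
  segments$label <- lab
  segments$excluded <- is.na(lab) | lab %in% exclude | startsWith(lab, "i")
  segments[order(segments$onset), , drop = FALSE]
}

#' Select the first-n renditions of one cell
#'
#' Implements the analysis convention of using the first `n` renditions (by
#' onset time) of a syllable type within one (bird, context, phase) session.
#'
#' @param renditions data.frame of one cell's labeled renditions (must carry
#'   an `onset` column).
#' @param n number of renditions to keep (default 20).
#' @return the first `n` rows by onset, or `NULL` (with a warning) when
#'   fewer than `n` renditions are available — the cell is excluded.
#' @export
select_renditions <- function(renditions, n = 20) {
  renditions <- renditions[order(renditions$onset), , drop = FALSE]
  if (nrow(renditions) < n) {
    warning(sprintf("cell has %d < %d renditions; excluded from analysis",
                    nrow(renditions), n))
    return(NULL)
  }
  out <- renditions[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
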