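# Immunoblot densitometry: background correction, loading-control
# normalization, group comparison, and the immunohistochemistry fiber-loss
# percentage.

#' Background-corrected band volume
#'
#' Raw densitometric volume minus a same-size background region. Negative
#' results (background exceeding the band — a measurement problem worth
#' surfacing) are clipped to zero and flagged via the `clipped` attribute.
#'
#' @param raw,background non-negative densitometric volumes.
#' @return corrected volume(s) with logical attribute `clipped`.
#' @export
corrected_volume <- function(raw, background) {
  stopifnot(all(raw >= 0), all(background >= 0))
  v <- raw - background
  clipped <- v < 0
  v[clipped] <- 0
  structure(v, clipped = clipped)
}

#' Loading-control-normalized signal
#'
#' Corrected target volume divided by the corrected loading-control (GAPDH)
#' volume of the same lane; undefined (NA) when the control is zero, in
#' which case the lane should be excluded.
#'
#' @param target_corrected corrected target volume(s).
#' @param gapdh_corrected corrected loading-control volume(s).
#' @return unitless ratio(s); NA where the control is zero.
#' @export
normalized_signal <- function(target_corrected, gapdh_corrected) {
  stopifnot(all(target_corrected >= 0), all(gapdh_corrected >= 0))
  out <- ifelse(gapdh_corrected > 0, target_corrected / gapdh_corrected,
                NA_real_)
  if (anyNA(out)) warning("zero loading control: lane(s) excluded (NA)")
  out
}

#' Normalize a lane table
#'
#' Applies background correction and per-lane loading-control normalization
#' to a densitometry table with one row per (sample, target) band.
#'
#' @param lanes data.frame with columns `sample`, `region`, `target`,
#'   `raw_volume`, `background_volume`; each sample must include a `GAPDH`
#'   row per region.
#' @return data.frame of non-control bands with added `corrected` and
#'   `normalized` columns.
#' @export
normalize_lanes <- function(lanes) {
  need <- c("sample", "region", "target", "raw_volume", "background_volume")
  stopifnot(all(need %in% names(lanes)))
  lanes$corrected <- as.numeric(corrected_volume(lanes$raw_volume,
                                                 lanes$background_volume))
  ctrl <- lanes[lanes$target == "GAPDH", c("sample", "region", "corrected")]
  names(ctrl)[3] <- "gapdh_corrected"
  out <- merge(lanes[lanes$target != "GAPDH", ], ctrl,
               by = c("sample", "region"), all.x = TRUE)
  out$normalized <- normalized_signal(out$corrected, out$gapdh_corrected)
  out
}

#' Compare biomarker levels between groups
#'
#' Unpaired resampling test on the group difference (mean statistic by
#' default, the configurable median alternative available), confirmed by a
#' Mann-Whitney U test.
#'
#' @param group_a,group_b normalized signal values (e.g. treated vs vehicle).
#' @param n_iter,seed passed to the resampling test.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return list with `resampling` (a `resampling_test`) and `mann_whitney`
#'   (list with `U`, `p_value`).
#' @export
compare_biomarker_groups <- function(group_a, group_b, n_iter = 10000,
                                     seed = 1,
                                     statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  rs <- resampling_unpaired_median_test(group_a, group_b, n_iter = n_iter,
                                        seed = seed, statistic = statistic)
  list(resampling = rs, mann_whitney = mann_whitney_u(group_a, group_b))
}

#' TH fiber-loss percentage
#'
#' Percentage loss of mean staining intensity in the treated hemisphere
#' relative to vehicle: 100 * (1 - treated/vehicle). Negative values
#' (treated brighter than vehicle) are returned but flagged.
#'
#' @param mean_intensity_treated,mean_intensity_vehicle mean ROI
#'   intensities; vehicle must be positive.
#' @return loss percentage with logical attribute `negative_loss`.
#' @export
fiber_loss_percent <- function(mean_intensity_treated,
                               mean_intensity_vehicle) {
  stopifnot(all(mean_intensity_vehicle > 0))
  loss <- 100 * (1 - mean_intensity_treated / mean_intensity_vehicle)
  if (any(loss < 0)) {
    warning("treated intensity exceeds vehicle: negative loss, flagged")
  }
  structure(loss, negative_loss = loss < 0)
}
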