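# Effect sizes, condition comparisons and the treatment-attribution
# decision rule.

#' Bounded effect size (A - B) / (A + B)
#'
#' A scale-free contrast between two non-negative measures, bounded in
#' [-1, 1], zero at equality and antisymmetric in its arguments. For
#' surgery comparisons A = post and B = pre (negative values mean the metric
#' was greater before injection); for social-context comparisons A = FD and
#' B = UD (negative values mean the metric is greater in UD).
#'
#' @param a,b non-negative measures with `a + b > 0`.
#' @return value in [-1, 1].
#' @export
effect_size <- function(a, b) {
  stopifnot(all(a >= 0), all(b >= 0))
  s <- a + b
  out <- ifelse(s > 0, (a - b) / s, NA_real_)
  if (anyNA(out)) {
    warning("a + b = 0: effect size undefined, flagged NA")
  }
  out
}

# per-cell summary of one feature over renditions
cell_measure <- function(x, measure) {
  if (measure == "mean") mean(x, na.rm = TRUE) else cv(x[is.finite(x)])
}

#' Per-syllable effect sizes from a feature table
#'
#' Computes one effect size per (bird, syllable, feature) for either the
#' surgery comparison (A = post, B = pre, within a context) or the
#' social-context comparison (A = FD, B = UD, within a phase). For
#' `measure = "cv"`, A and B are the rendition CVs of the feature in each
#' condition; for `"mean"`, the rendition means. Wiener entropy is taken as
#' a magnitude so the non-negativity requirement of the formula holds.
#'
#' @param feature_table data.frame with columns `bird`, `syllable`,
#'   `context`, `phase` plus feature columns; one row per rendition.
#' @param feature feature column name.
#' @param comparison `"surgery"` or `"social_context"`.
#' @param measure `"mean"` or `"cv"`.
#' @param context for `comparison = "surgery"`: which context to analyze.
#' @param phase for `comparison = "social_context"`: which phase to analyze.
#' @return data.frame with columns `bird`, `syllable`, `feature`,
#'   `comparison`, `measure`, `A`, `B`, `value`.
#' @export
per_syllable_effects <- function(feature_table, feature,
                                 comparison = c("surgery", "social_context"),
                                 measure = c("mean", "cv"),
                                 context = "UD", phase = "post") {
  comparison <- match.arg(comparison)
  measure <- match.arg(measure)
  x <- feature_table
  vals <- x[[feature]]
  if (feature == "wiener_entropy") vals <- abs(vals)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("effect sizes require non-negative measures; pass magnitudes")
  }
  x$.value <- vals
  if (comparison == "surgery") {
    x <- x[x$context == context, ]
    cond_col <- "phase"; cond_a <- "post"; cond_b <- "pre"
  } else {
    x <- x[x$phase == phase, ]
    cond_col <- "context"; cond_a <- "FD"; cond_b <- "UD"
  }
  key <- interaction(x$bird, x$syllable, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- x[key == k, ]
    va <- sub$.value[sub[[cond_col]] == cond_a]
    vb <- sub$.value[sub[[cond_col]] == cond_b]
    all_na <- all(!is.finite(va)) && all(!is.finite(vb))
    va <- va[is.finite(va)]
    vb <- vb[is.finite(vb)]
    if (length(va) < 2 || length(vb) < 2) {
      # silently skip cells where the feature is undefined for the
      # syllable kind (e.g. FF of a noise burst); warn on partial loss
      if (!all_na) warning("syllable ", k, " missing a condition; dropped")
      return(NULL)
    }
    a <- cell_measure(va, measure)
    b <- cell_measure(vb, measure)
    data.frame(bird = sub$bird[1], syllable = sub$syllable[1],
               feature = feature, comparison = comparison,
               measure = measure, A = a, B = b,
               value = effect_size(a, b), stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Compare effect-size distributions between conditions
#'
#' Delegates to the unpaired resampling test on the effect values (e.g.
#' treated vs vehicle birds, or UD vs FD), median statistic by default with
#' the mean-difference dialect available.
#'
#' @param effects_a,effects_b data.frames from [per_syllable_effects()] (or
#'   numeric vectors of effect values).
#' @param n_iter,seed passed to [resampling_unpaired_median_test()].
#' @param statistic `"median"` or `"mean"`.
#' @return a `resampling_test`.
#' @export
compare_conditions <- function(effects_a, effects_b, n_iter = 10000,
                               seed = 1, statistic = c("median", "mean")) {
  va <- if (is.data.frame(effects_a)) effects_a$value else effects_a
  vb <- if (is.data.frame(effects_b)) effects_b$value else effects_b
  va <- va[is.finite(va)]
  vb <- vb[is.finite(vb)]
  stopifnot(length(va) >= 1, length(vb) >= 1)
  resampling_unpaired_median_test(va, vb, n_iter = n_iter, seed = seed,
                                  statistic = match.arg(statistic))
}

#' Treatment-attribution decision rule
#'
#' A treatment effect is attributed when the treated group's p-value is
#' below alpha AND the vehicle group's is not. When both are significant the
#' verdict is `both_changed` (a possible confound made explicit); when
#' neither is, `no_effect`.
#'
#' @param p_treated,p_vehicle p-values from the within-group tests.
#' @param alpha significance level.
#' @return object of class `comparison_verdict`: list with `p_treated`,
#'   `p_vehicle`, `alpha`, `verdict`.
#' @export
treatment_decision <- function(p_treated, p_vehicle, alpha = 0.05) {
  stopifnot(is.finite(p_treated), is.finite(p_vehicle),
            p_treated >= 0, p_treated <= 1, p_vehicle >= 0, p_vehicle <= 1)
  verdict <- if (p_treated < alpha && p_vehicle >= alpha) {
    "treatment_effect"
  } else if (p_treated < alpha && p_vehicle < alpha) {
    "both_changed"
  } else {
    "no_effect"
  }
  structure(list(p_treated = p_treated, p_vehicle = p_vehicle,
                 alpha = alpha, verdict = verdict),
            class = "comparison_verdict")
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (treated p = %.4g, vehicle p = %.4g, alpha = %g)\n",
              x$verdict, x$p_treated, x$p_vehicle, x$alpha))
  invisible(x)
}
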