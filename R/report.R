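# Study-level analysis and summary-table reporting.

# Per-syllable cell summaries: one row per (bird, syllable, treatment,
# context, phase) with the mean and CV of each feature over renditions.
syllable_cell_summary <- function(feature_table, features) {
  key <- interaction(feature_table$bird, feature_table$syllable,
                     feature_table$context, feature_table$phase, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- feature_table[key == k, ]
    out <- data.frame(bird = sub$bird[1], syllable = sub$syllable[1],
                      treatment = sub$treatment[1], context = sub$context[1],
                      phase = sub$phase[1], n_renditions = nrow(sub),
                      stringsAsFactors = FALSE)
    for (f in features) {
      v <- sub[[f]]
      if (f == "wiener_entropy") v <- abs(v)
      v <- v[is.finite(v)]
      out[[paste0(f, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(f, "_cv")]] <- if (length(v) >= 2 && mean(v) != 0)
        stats::sd(v) / mean(v) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Build a summary report of song features
#'
#' For every (treatment x context x feature), reports the pre- and
#' post-surgery means with SEM across syllables, the rendition CVs with
#' their SEM, p-values from the resampling paired test on per-syllable
#' values pre vs post, and bootstrap power — mirroring the standard
#' song-feature summary-table layout. No multiple-testing correction is
#' applied across features (matching the analysis convention this package
#' implements); interpret the table accordingly.
#'
#' @param feature_table per-rendition feature table (columns `bird`,
#'   `treatment`, `context`, `phase`, `syllable`, `rendition` + features).
#' @param features feature column names to report.
#' @param n_iter resampling iterations per test.
#' @param seed master seed; per-test seeds are derived deterministically.
#' @param power_outer bootstrap resamples for the power column (0 skips
#'   power, returning NA).
#' @return data.frame, one row per (treatment, context, feature).
#' @export
build_report <- function(feature_table, features = c("duration_ms", "f0",
                                                     "amplitude"),
                         n_iter = 2000, seed = 1, power_outer = 200) {
  cells <- syllable_cell_summary(feature_table, features)
  rows <- list()
  i <- 0L
  for (trt in unique(cells$treatment)) {
    for (ctx in unique(cells$context)) {
      sub <- cells[cells$treatment == trt & cells$context == ctx, ]
      pre <- sub[sub$phase == "pre", ]
      post <- sub[sub$phase == "post", ]
      key <- c("bird", "syllable")
      merged <- merge(pre, post, by = key, suffixes = c("_pre", "_post"))
      for (f in features) {
        i <- i + 1L
        mpre <- merged[[paste0(f, "_mean_pre")]]
        mpost <- merged[[paste0(f, "_mean_post")]]
        cpre <- merged[[paste0(f, "_cv_pre")]]
        cpost <- merged[[paste0(f, "_cv_post")]]
        ok_m <- is.finite(mpre) & is.finite(mpost)
        ok_c <- is.finite(cpre) & is.finite(cpost)
        s1 <- derive_seed(seed, i, 1L)
        s2 <- derive_seed(seed, i, 2L)
        p_mean <- if (sum(ok_m) >= 2)
          resampling_paired_test(mpre[ok_m], mpost[ok_m], n_iter, s1)$p_value
        else NA_real_
        p_cv <- if (sum(ok_c) >= 2)
          resampling_paired_test(cpre[ok_c], cpost[ok_c], n_iter, s2)$p_value
        else NA_real_
        pw_mean <- pw_cv <- NA_real_
        if (power_outer > 0 && sum(ok_m) >= 2) {
          pw_mean <- resampling_power(
            list(pre = mpre[ok_m], post = mpost[ok_m]), "paired",
            n_outer = power_outer, n_iter = min(n_iter, 500),
            seed = derive_seed(seed, i, 3L))$power
        }
        if (power_outer > 0 && sum(ok_c) >= 2) {
          pw_cv <- resampling_power(
            list(pre = cpre[ok_c], post = cpost[ok_c]), "paired",
            n_outer = power_outer, n_iter = min(n_iter, 500),
            seed = derive_seed(seed, i, 4L))$power
        }
        rows[[i]] <- data.frame(
          treatment = trt, context = ctx, feature = f,
          n_syllables = nrow(merged),
          mean_pre = mean(mpre[ok_m]), sem_pre = sem(mpre[ok_m]),
          mean_post = mean(mpost[ok_m]), sem_post = sem(mpost[ok_m]),
          p_mean = p_mean, power_mean = pw_mean,
          cv_pre = mean(cpre[ok_c]), cv_sem_pre = sem(cpre[ok_c]),
          cv_post = mean(cpost[ok_c]), cv_sem_post = sem(cpost[ok_c]),
          p_cv = p_cv, power_cv = pw_cv, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze a study feature table
#'
#' The top-level analysis: per (context, feature, measure) it runs the
#' within-group resampling paired test (per-syllable pre vs post) separately
#' for treated and vehicle birds, applies the treatment-attribution decision
#' rule, and computes across-group effect-size comparisons (treated vs
#' vehicle surgery effect sizes, unpaired median test).
#'
#' @param feature_table per-rendition feature table (see [build_report()]).
#' @param features feature columns to analyze.
#' @param measures `"mean"`, `"cv"` or both.
#' @param n_iter resampling iterations.
#' @param seed master seed.
#' @param alpha significance level for verdicts.
#' @param effect_tests also run the across-group effect-size comparisons
#'   (set `FALSE` to compute verdicts only).
#' @return object of class `song_study_analysis`: list with `verdicts`
#'   (data.frame), `effect_tests` (data.frame or NULL), `cells`, `alpha`,
#'   `seed`.
#' @export
analyze_study <- function(feature_table, features = c("f0", "duration_ms",
                                                      "amplitude"),
                          measures = c("mean", "cv"), n_iter = 2000,
                          seed = 1, alpha = 0.05, effect_tests = TRUE) {
  cells <- syllable_cell_summary(feature_table, features)
  verdicts <- list()
  etests <- list()
  i <- 0L
  for (ctx in unique(cells$context)) {
    for (f in features) {
      for (m in measures) {
        i <- i + 1L
        col <- paste0(f, "_", m)
        p_group <- sapply(c("sixohda", "vehicle"), function(trt) {
          sub <- cells[cells$treatment == trt & cells$context == ctx, ]
          merged <- merge(sub[sub$phase == "pre", c("bird", "syllable", col)],
                          sub[sub$phase == "post", c("bird", "syllable", col)],
                          by = c("bird", "syllable"),
                          suffixes = c("_pre", "_post"))
          pre <- merged[[paste0(col, "_pre")]]
          post <- merged[[paste0(col, "_post")]]
          ok <- is.finite(pre) & is.finite(post)
          if (sum(ok) < 2) return(NA_real_)
          resampling_paired_test(pre[ok], post[ok], n_iter,
                                 derive_seed(seed, i, match(trt, c(
                                   "sixohda", "vehicle"))))$p_value
        })
        if (anyNA(p_group)) next
        dec <- treatment_decision(p_group[["sixohda"]], p_group[["vehicle"]],
                                  alpha)
        verdicts[[length(verdicts) + 1]] <- data.frame(
          context = ctx, feature = f, measure = m,
          p_treated = dec$p_treated, p_vehicle = dec$p_vehicle,
          verdict = dec$verdict, stringsAsFactors = FALSE)
        if (!effect_tests) next
        # across-group comparison of surgery effect sizes
        eff <- suppressWarnings(
          per_syllable_effects(feature_table, f, "surgery", m,
                               context = ctx))
        if (is.null(eff)) next
        ea <- eff$value[startsWith(as.character(eff$bird), "t")]
        eb <- eff$value[startsWith(as.character(eff$bird), "v")]
        ea <- ea[is.finite(ea)]
        eb <- eb[is.finite(eb)]
        if (length(ea) >= 2 && length(eb) >= 2) {
          ct <- compare_conditions(ea, eb, n_iter,
                                   derive_seed(seed, i, 5L))
          etests[[length(etests) + 1]] <- data.frame(
            context = ctx, feature = f, measure = m,
            median_effect_treated = stats::median(ea),
            median_effect_vehicle = stats::median(eb),
            p_across_groups = ct$p_value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(verdicts = do.call(rbind, verdicts),
                 effect_tests = do.call(rbind, etests),
                 cells = cells, alpha = alpha, seed = seed,
                 n_iter = n_iter),
            class = "song_study_analysis")
}

#' @export
print.song_study_analysis <- function(x, ...) {
  cat("Song study analysis\n")
  cat(sprintf("  %d syllable cells, alpha = %g, %d resampling iterations\n",
              nrow(x$cells), x$alpha, x$n_iter))
  cat("Verdicts:\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.song_study_analysis <- function(object, ...) {
  v <- object$verdicts
  cat("Treatment-attribution summary\n")
  for (ctx in unique(v$context)) {
    sub <- v[v$context == ctx, ]
    hits <- sub[sub$verdict == "treatment_effect", ]
    cat(sprintf("  %s: %d/%d measures with a treatment effect", ctx,
                nrow(hits), nrow(sub)))
    if (nrow(hits)) {
      cat(" (", paste(paste0(hits$feature, "/", hits$measure),
                      collapse = ", "), ")", sep = "")
    }
    cat("\n")
  }
  if (!is.null(object$effect_tests)) {
    cat("Across-group effect-size tests (unpaired median):\n")
    print(object$effect_tests, row.names = FALSE)
  }
  invisible(object)
}
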