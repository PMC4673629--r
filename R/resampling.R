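# Resampling statistics: the tests used throughout the analysis.
# P-values use the add-one (Davison-Hinkley) correction
# p = (1 + #{null >= observed}) / (1 + n_iter), so p is always in (0, 1].

# median via partial sort, avoiding generic-dispatch overhead in the
# permutation loop
fast_median <- function(x) {
  n <- length(x)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort.int(x, partial = half)[half]
  } else {
    s <- sort.int(x, partial = c(half, half + 1L))
    (s[half] + s[half + 1L]) / 2
  }
}

new_resampling_result <- function(observed, null_stats, p_value, n_iter,
                                  seed, kind) {
  structure(list(observed_statistic = observed, p_value = p_value,
                 n_iterations = n_iter, seed = seed, statistic_kind = kind,
                 null_mean = mean(null_stats), null_sd = stats::sd(null_stats)),
            class = "resampling_test")
}

#' @export
print.resampling_test <- function(x, ...) {
  cat(sprintf("Resampling test (%s)\n", x$statistic_kind))
  cat(sprintf("  observed statistic: %.6g\n", x$observed_statistic))
  cat(sprintf("  p-value: %.4g  (%d iterations, seed %d)\n", x$p_value,
              x$n_iterations, x$seed))
  cat(sprintf("  null mean (sd): %.4g (%.4g)\n", x$null_mean, x$null_sd))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; the variability currency
#' of the whole analysis.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return unitless CV.
#' @export
cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("cv needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("cv undefined for zero mean")
  stats::sd(values) / m
}

#' Resampling paired test (sign-flip null)
#'
#' Statistic: mean(post - pre). The null is simulated by independently
#' flipping the sign of each pair's difference; the two-sided p-value is the
#' add-one-corrected fraction of null statistics at least as extreme in
#' absolute value.
#'
#' @param pre,post paired numeric vectors.
#' @param n_iter number of resampling iterations.
#' @param seed integer seed.
#' @return a `resampling_test`.
#' @export
resampling_paired_test <- function(pre, post, n_iter = 10000, seed = 1) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  obs <- mean(d)
  if (all(d == 0)) {
    return(new_resampling_result(0, numeric(n_iter), 1, n_iter, seed,
                                 "paired_mean_diff"))
  }
  null_stats <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), length(d) * n_iter, replace = TRUE),
                    nrow = length(d))
    colMeans(signs * d)
  })
  p <- (1 + sum(abs(null_stats) >= abs(obs) - 1e-12)) / (1 + n_iter)
  new_resampling_result(obs, null_stats, p, n_iter, seed, "paired_mean_diff")
}

#' Resampling unpaired test on medians (or means)
#'
#' Statistic: median(a) - median(b) (or the mean difference when
#' `statistic = "mean"`). The null permutes group labels over the pooled
#' values; two-sided p with add-one correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return a `resampling_test`.
#' @export
resampling_unpaired_median_test <- function(a, b, n_iter = 10000, seed = 1,
                                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(length(a) >= 1, length(b) >= 1)
  stat_fun <- if (statistic == "median") fast_median else mean
  obs <- stat_fun(a) - stat_fun(b)
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n, na)
      stat_fun(pooled[idx]) - stat_fun(pooled[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(obs) - 1e-12)) / (1 + n_iter)
  kind <- if (statistic == "median") "unpaired_median_diff" else
    "unpaired_mean_diff"
  new_resampling_result(obs, null_stats, p, n_iter, seed, kind)
}

f_statistic <- function(values, groups) {
  k <- length(unique(groups))
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[match(groups, names(gm))])^2)
  if (ssw == 0) return(NA_real_)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Resampling one-way ANOVA
#'
#' Statistic: the usual between/within variance ratio (F-form). The null
#' permutes observations across groups; the p-value is one-sided
#' (large F = group effect) with add-one correction.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param n_iter iterations.
#' @param seed integer seed.
#' @return a `resampling_test`.
#' @export
resampling_oneway_anova <- function(groups, n_iter = 10000, seed = 1) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), vapply(groups, length, 1L))
  obs <- f_statistic(values, labels)
  if (!is.finite(obs)) {
    if (stats::var(values) == 0) {
      stop("zero within-group variance everywhere; F undefined")
    }
    obs <- Inf  # perfectly separated constant groups
  }
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      f <- f_statistic(values, labels[sample.int(length(labels))])
      if (is.finite(f)) f else Inf
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= obs - 1e-12)) / (1 + n_iter)
  new_resampling_result(obs, null_stats[is.finite(null_stats)], p, n_iter,
                        seed, "anova_F")
}

#' Mann-Whitney U test
#'
#' Confirmation test for group comparisons: exact when both groups are small
#' (<= 8, no ties), normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors.
#' @return list with `U` and two-sided `p_value`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- length(a) <= 8 && length(b) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Bootstrap power of a resampling test
#'
#' Case-resampling bootstrap power: resample the observed data with
#' replacement (preserving pairing or grouping), apply the test, and report
#' the fraction of resamples with p < alpha. This is a bootstrap power
#' estimate, labeled as such.
#'
#' @param data for `test = "paired"`, a list with `pre` and `post`; for
#'   `"unpaired_median"` or `"unpaired_mean"`, a list with `a` and `b`.
#' @param test which wrapped test to use.
#' @param alpha significance level.
#' @param n_outer bootstrap resamples.
#' @param n_iter inner resampling iterations per test.
#' @param seed integer seed.
#' @return list with `power`, `alpha`, `n_iterations` (= `n_outer`), `seed`,
#'   `method = "bootstrap"`.
#' @export
resampling_power <- function(data, test = c("paired", "unpaired_median",
                                            "unpaired_mean"),
                             alpha = 0.05, n_outer = 1000, n_iter = 1000,
                             seed = 1) {
  test <- match.arg(test)
  seeds <- with_seed(seed, sample.int(2^30, n_outer))
  hits <- vapply(seq_len(n_outer), function(i) {
    p <- with_seed(seeds[i], {
      if (test == "paired") {
        idx <- sample.int(length(data$pre), replace = TRUE)
        resampling_paired_test(data$pre[idx], data$post[idx],
                               n_iter = n_iter, seed = seeds[i])$p_value
      } else {
        ia <- sample.int(length(data$a), replace = TRUE)
        ib <- sample.int(length(data$b), replace = TRUE)
        stat <- if (test == "unpaired_median") "median" else "mean"
        resampling_unpaired_median_test(data$a[ia], data$b[ib],
                                        n_iter = n_iter, seed = seeds[i],
                                        statistic = stat)$p_value
      }
    })
    p < alpha
  }, logical(1))
  list(power = mean(hits), alpha = alpha, n_iterations = n_outer,
       seed = seed, method = "bootstrap")
}
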