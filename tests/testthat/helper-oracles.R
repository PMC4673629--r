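# Independent enumeration oracles for the resampling tests. These never call
# the package's resampling code paths.

# Exhaustive sign-flip null for a paired mean-difference test: all 2^n sign
# patterns, two-sided exceedance probability.
oracle_signflip_p <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_stats <- signs %*% d / n
  mean(abs(null_stats) >= abs(obs) - 1e-12)
}

# Exhaustive label-permutation null for the unpaired median-difference test:
# all C(n, na) assignments of pooled values to group a.
oracle_permutation_median_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- median(a) - median(b)
  idx <- utils::combn(n, length(a))
  null_stats <- apply(idx, 2, function(i) {
    median(pooled[i]) - median(pooled[-i])
  })
  mean(abs(null_stats) >= abs(obs) - 1e-12)
}

# Exact Mann-Whitney two-sided p by enumerating every group assignment of
# the pooled sample (no ties assumed): p = 2 * min(P(U <= u), P(U >= u)),
# capped at 1 (the convention of the exact distribution).
oracle_mwu <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) # U for x over y
  u_obs <- u_of(a, b)
  idx <- utils::combn(n, na)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p_value = min(p, 1))
}

# Sample CV of log-normal multiplicative jitter, by direct simulation
# (used to freeze Monte-Carlo expectations for generator calibration).
oracle_lognormal_cv <- function(cv, n, seed) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  x <- rlnorm(n, -sdlog^2 / 2, sdlog)
  sd(x) / mean(x)
}
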