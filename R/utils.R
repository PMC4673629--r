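#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)`, restoring the caller's RNG state
#' afterwards so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), mode = "integer", inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: fold integer keys into a 31-bit hash so
# every (bird, context, phase, syllable, rendition) cell gets its own stream
# reproducible from the master seed alone.
derive_seed <- function(master, ...) {
  keys <- c(...)
  h <- as.double(master) %% 2147480009
  for (k in keys) {
    # multiplier kept small enough that h * mult stays below 2^53
    h <- (h * 69069 + as.double(k) + 12345) %% 2147480009
  }
  as.integer(h)
}

# Log-normal multiplier with unit mean and exact coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

db_to_linear <- function(db) 10^(db / 20)
linear_to_db <- function(x) 20 * log10(pmax(x, 1e-12))
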