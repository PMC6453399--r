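# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# Derive a child seed from a master seed and a counter. Linear
# congruential mixing keeps everything inside 32-bit integer range while
# giving distinct, reproducible streams per (seed, k).
deriveSeed <- function(seed, k) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + as.double(k) * 30269 + 11) %% 2147483647)
}

# Column variances of a matrix (denominator n - 1); rows are replicates.
colVars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  colSums((m - rep(mu, each = n))^2) / (n - 1)
}

# near-equality for doubles, relative to scale
relClose <- function(a, b, tol = 1e-9) {
  abs(a - b) <= tol * pmax(1, abs(a), abs(b))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
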