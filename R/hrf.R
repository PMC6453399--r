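#' @include AllClasses.R
NULL

# continuous (unnormalized) double-gamma response
.hrfRaw <- function(t, params) {
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    out[pos] <-
      stats::dgamma(tp, shape = params@peakDelay / params@peakDispersion,
                    scale = params@peakDispersion) -
      params@undershootRatio *
        stats::dgamma(tp, shape = params@undershootDelay / params@undershootDispersion,
                      scale = params@undershootDispersion)
  }
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the double-gamma HRF at times `t` (seconds relative to
#' stimulus onset). The response is causal (`h(t) = 0` for `t <= 0`) and
#' normalized so its continuous peak equals 1; with default parameters
#' the peak sits near 5 s (the 6 s gamma peak pulled slightly earlier by
#' the undershoot term).
#'
#' @param t numeric vector of seconds relative to onset.
#' @param params an [HRFParams-class] object.
#' @return numeric vector `h(t)` with peak amplitude 1.
#' @examples
#' tt <- seq(-5, 20, by = 0.5)
#' h <- hrf(tt)
#' range(h)
#' @export
hrf <- function(t, params = hrfParams()) {
  methods::validObject(params)
  # the double-gamma is not unimodal (positive peak, later undershoot):
  # locate the global maximum on a coarse grid, then refine locally
  upper <- max(params@undershootDelay, params@peakDelay) * 3
  grid <- seq(1e-4, upper, length.out = 2048L)
  vals <- .hrfRaw(grid, params)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  peak <- stats::optimize(function(x) .hrfRaw(x, params),
                          interval = c(lo, hi), maximum = TRUE,
                          tol = 1e-10)$objective
  if (peak <= 0)
    stopf("HRF has no positive peak for these parameters")
  .hrfRaw(t, params) / peak
}
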