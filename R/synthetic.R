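#' @include AllClasses.R hrf.R
NULL

# Effect amplitude of the "effect-strong" preset. Frozen from the
# closed-form Mahalanobis separation of the generative model on the
# preset's 200-point epoch grid: with uniform loadings and white shared
# noise the Bayes discriminant reduces to the channel mean followed by a
# matched temporal filter, d(beta) = beta * sqrt(sum(h^2) /
# (sigma_sh^2 + sigma_ch^2 / C)), and beta solves
# Phi(d/2) = 0.9. Verified against the Monte-Carlo likelihood-ratio
# oracle bayesAccuracy() in the test suite.
.effectStrongBeta <- 0.443389

#' Implied inter-channel correlation of a synthetic configuration
#'
#' Under the generative model, two channels share the latent process and
#' differ by channel noise and drift, so their stationary correlation is
#' `sigma_shared^2 / (sigma_shared^2 + sigma_chan^2 + sigma_drift^2 / (1 - phi^2))`
#' (the drift term vanishes when the drift is off).
#'
#' @param config a [SyntheticConfig-class].
#' @return correlation in `[0, 1]`.
#' @export
channelCorrelation <- function(config) {
  s2 <- config@sharedNoiseSd^2
  c2 <- config@channelNoiseSd^2
  d2 <- if (config@driftInnovationSd > 0)
    config@driftInnovationSd^2 / (1 - config@driftAr^2) else 0
  if (s2 + c2 + d2 == 0) return(0)
  s2 / (s2 + c2 + d2)
}

#' Generate a synthetic trial dataset
#'
#' Draws a [TrialDataset-class] from the generative model of
#' [SyntheticConfig-class]: per trial, channel c and time tau,
#' `x = beta * h(tau) * g_c * [yes] + sigma_sh * z(tau) +
#' sigma_ch * eps_c(tau) + d_c(tau)`, with the shared process z white in
#' time, channel noise independent, and an optional stationary AR(1)
#' drift per channel; everything is drawn fresh per trial. Output is
#' bit-reproducible given the config (including its seed) and passes
#' [validateDataset()].
#'
#' @param config a valid [SyntheticConfig-class].
#' @return a [TrialDataset-class] with days `"day1"`, ..., sessions
#'   `"s1"`, ... and patient id `"synthetic"`.
#' @examples
#' d <- generateDataset(syntheticConfig(sessionsPerDay = 2,
#'   trialsPerCondition = 3, nChannels = 4, seed = 42))
#' d
#' @export
generateDataset <- function(config) {
  methods::validObject(config)
  tax <- timeAxis(config)
  nT <- length(tax)
  C <- config@nChannels
  g <- rep(config@channelLoadings, length.out = C)
  h <- hrf(tax, config@hrfParams)
  sigSh <- config@sharedNoiseSd
  sigCh <- config@channelNoiseSd
  phi <- config@driftAr
  sigD <- config@driftInnovationSd
  signalYes <- config@effectAmplitude * outer(g, h)

  drawTrial <- function(isYes) {
    x <- matrix(sigSh * rnorm(nT), nrow = C, ncol = nT, byrow = TRUE) +
      matrix(sigCh * rnorm(C * nT), nrow = C)
    if (sigD > 0) {
      init <- rnorm(C, sd = sigD / sqrt(1 - phi^2))
      innov <- matrix(sigD * rnorm(C * nT), nrow = C)
      for (ch in seq_len(C))
        x[ch, ] <- x[ch, ] + as.numeric(
          stats::filter(innov[ch, ], phi, method = "recursive",
                        init = init[ch]))
    }
    if (isYes) x + signalYes else x
  }
  drawCondition <- function(n, isYes) {
    arr <- array(0, c(n, C, nT))
    for (tr in seq_len(n)) arr[tr, , ] <- drawTrial(isYes)
    arr
  }

  withSeed(config@seed, {
    daysList <- lapply(seq_len(config@nDays), function(di) {
      sess <- lapply(seq_len(config@sessionsPerDay), function(si) {
        SessionRecord(sprintf("s%d", si),
                      drawCondition(config@trialsYes, TRUE),
                      drawCondition(config@trialsNo, FALSE))
      })
      DayRecord(sprintf("day%d", di), sess)
    })
    TrialDataset("synthetic", daysList, tax, config@samplingRate,
                 nChannels = C)
  })
}

#' Documented synthetic presets
#'
#' * `"null-highcorr"`: no condition effect (beta = 0), 20 highly
#'   correlated channels (rho = 0.95), 1 day of 10 sessions with 10
#'   trials per condition, 200 timepoints (epoch \[-5, 20) s at 8 Hz).
#'   The configuration under which a correct timepoint-wise test is
#'   calibrated and the flawed averaging order is wildly anticonservative.
#' * `"effect-strong"`: same noise structure over 4 days x 10 sessions,
#'   with beta = 0.443389 calibrated so the Bayes-optimal single-trial
#'   accuracy of the generative model is approximately 0.9 (see
#'   [bayesAccuracy()]).
#' * `"imbalanced"`: as `"null-highcorr"` but 7 yes / 3 no trials per
#'   session, to exercise undersampling-based class balancing.
#'
#' @param name preset name.
#' @param seed integer seed stored in the returned config.
#' @return a [SyntheticConfig-class].
#' @examples
#' syntheticPreset("null-highcorr", seed = 7)
#' @export
syntheticPreset <- function(name = c("null-highcorr", "effect-strong",
                                     "imbalanced"), seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("null-highcorr", "effect-strong", "imbalanced"))
    stopf("unknown preset '%s'; available presets: null-highcorr, effect-strong, imbalanced",
          as.character(name)[1])
  name <- name[1]
  base <- function(...) {
    syntheticConfig(nChannels = 20L, epochWindow = c(-5, 20), samplingRate = 8,
                    sharedNoiseSd = sqrt(0.95), channelNoiseSd = sqrt(0.05),
                    seed = seed, ...)
  }
  switch(name,
    "null-highcorr" = base(nDays = 1L, sessionsPerDay = 10L,
                           trialsPerCondition = 10L, effectAmplitude = 0),
    "effect-strong" = base(nDays = 4L, sessionsPerDay = 10L,
                           trialsPerCondition = 10L,
                           effectAmplitude = .effectStrongBeta),
    "imbalanced" = base(nDays = 1L, sessionsPerDay = 10L,
                        trialsYes = 7L, trialsNo = 3L, effectAmplitude = 0))
}

#' Monte-Carlo Bayes-optimal accuracy of a synthetic configuration
#'
#' Simulates single trials from the generative model and classifies them
#' with the likelihood-ratio rule of the true model (equal priors). With
#' white shared noise the two classes are Gaussian with common
#' per-timepoint covariance `Sigma_c = sigma_sh^2 J + sigma_ch^2 I`, so
#' the discriminant is `sum_tau beta h(tau) a' x(tau)` with
#' `a = Sigma_c^{-1} g` (Sherman-Morrison closed form), thresholded at
#' its class midpoint. Supports drift-free configurations only
#' (`driftAr = 0`, `driftInnovationSd = 0`), which is what the presets
#' use; the per-timepoint whitening is exact there.
#'
#' @param config a [SyntheticConfig-class] with the drift switched off.
#' @param nSim number of simulated trials (half per class).
#' @param seed integer seed for the simulation.
#' @return Monte-Carlo estimate of the Bayes accuracy.
#' @examples
#' bayesAccuracy(syntheticPreset("effect-strong"), nSim = 2000, seed = 1)
#' @export
bayesAccuracy <- function(config, nSim = 10000, seed = 1L) {
  methods::validObject(config)
  if (config@driftAr != 0 || config@driftInnovationSd != 0)
    stopf("bayesAccuracy supports drift-free configurations only (driftAr = 0, driftInnovationSd = 0)")
  tax <- timeAxis(config)
  nT <- length(tax)
  C <- config@nChannels
  g <- rep(config@channelLoadings, length.out = C)
  h <- hrf(tax, config@hrfParams)
  beta <- config@effectAmplitude
  if (beta == 0) return(0.5)
  s2 <- config@sharedNoiseSd^2
  c2 <- config@channelNoiseSd^2
  if (s2 + c2 == 0) return(1)
  # a = Sigma_c^{-1} g with Sigma_c = s2 * J + c2 * I (Sherman-Morrison)
  a <- (g - (s2 * sum(g) / (c2 + C * s2))) / c2
  ag <- sum(a * g)
  a1 <- sum(a)
  anorm <- sqrt(sum(a^2))
  w <- beta * h                       # temporal weights on the a-projection
  thresh <- 0.5 * beta * ag * sum(w * h)
  nHalf <- ceiling(nSim / 2)
  withSeed(seed, {
    simulate <- function(isYes) {
      correct <- 0L
      left <- nHalf
      while (left > 0L) {
        m <- min(left, 1000L)
        # a-projection of each trial's samples: signal + shared + channel parts
        U <- matrix(config@sharedNoiseSd * a1 * rnorm(m * nT) +
                      sqrt(c2) * anorm * rnorm(m * nT), nrow = m)
        if (isYes) U <- U + matrix(beta * ag * h, m, nT, byrow = TRUE)
        s <- as.numeric(U %*% w)
        correct <- correct + if (isYes) sum(s > thresh) else sum(s <= thresh)
        left <- left - m
      }
      correct
    }
    (simulate(TRUE) + simulate(FALSE)) / (2 * nHalf)
  })
}
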