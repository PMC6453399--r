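test_that("the epoch grid covers [start, end) at the sampling rate", {
  cfg <- syntheticConfig(epochWindow = c(-5, 20), samplingRate = 8)
  expect_length(timeAxis(cfg), 200L)
  cfg2 <- syntheticConfig(epochWindow = c(-5, 20), samplingRate = 2)
  tax <- timeAxis(cfg2)
  expect_length(tax, 50L)
  expect_equal(tax[1], -5)
  expect_equal(diff(tax)[1], 0.5)
})

test_that("configs without a pre-stimulus baseline are rejected", {
  expect_error(syntheticConfig(epochWindow = c(0, 20)), "baseline")
  expect_error(syntheticConfig(driftAr = 1), "driftAr")
  expect_error(syntheticConfig(sharedNoiseSd = -1), "sds")
})

test_that("silent null and noiseless effect are exact", {
  base <- list(sessionsPerDay = 1L, trialsPerCondition = 2L, nChannels = 3L,
               epochWindow = c(-2, 10), samplingRate = 2, sharedNoiseSd = 0,
               channelNoiseSd = 0, seed = 1L)
  d0 <- generateDataset(do.call(syntheticConfig, c(base, effectAmplitude = 0)))
  s0 <- allSessions(d0)[[1]]
  expect_identical(max(abs(s0@trialsYes)), 0)
  expect_identical(max(abs(s0@trialsNo)), 0)

  cfg <- do.call(syntheticConfig,
                 c(base, list(effectAmplitude = 2, channelLoadings = c(1, 0.5, 0))))
  d <- generateDataset(cfg)
  s <- allSessions(d)[[1]]
  h <- hrf(timeAxis(d))
  for (tr in 1:2) for (ch in 1:3)
    expect_equal(s@trialsYes[tr, ch, ], 2 * h * c(1, 0.5, 0)[ch],
                 tolerance = 1e-12)
  expect_identical(max(abs(s@trialsNo)), 0)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- syntheticConfig(sessionsPerDay = 2, trialsPerCondition = 2,
                         nChannels = 3, epochWindow = c(-1, 2), seed = 7,
                         driftAr = 0.5, driftInnovationSd = 0.2)
  a <- allSessions(generateDataset(cfg))[[1]]@trialsYes
  b <- allSessions(generateDataset(cfg))[[1]]@trialsYes
  expect_identical(a, b)
  cfg2 <- syntheticConfig(sessionsPerDay = 2, trialsPerCondition = 2,
                          nChannels = 3, epochWindow = c(-1, 2), seed = 8,
                          driftAr = 0.5, driftInnovationSd = 0.2)
  expect_false(identical(a, allSessions(generateDataset(cfg2))[[1]]@trialsYes))
})

test_that("generated datasets always pass validation", {
  for (seed in 1:3) {
    d <- generateDataset(syntheticConfig(sessionsPerDay = 2, trialsYes = 3,
                                         trialsNo = 1, nChannels = 2,
                                         epochWindow = c(-1, 3),
                                         driftAr = 0.9, driftInnovationSd = 0.1,
                                         seed = seed))
    expect_identical(validateDataset(d), character(0))
  }
})

test_that("empirical inter-channel correlation matches the closed form", {
  # sigma_shared = 3, sigma_chan = 1, phi = 0  ->  rho = 9/10
  cfg <- syntheticConfig(sessionsPerDay = 1, trialsPerCondition = 100,
                         nChannels = 2, epochWindow = c(-5, 45),
                         samplingRate = 2, sharedNoiseSd = 3,
                         channelNoiseSd = 1, seed = 11)
  expect_equal(channelCorrelation(cfg), 0.9)
  a <- allSessions(generateDataset(cfg))[[1]]@trialsYes
  n <- dim(a)[1] * dim(a)[3]
  expect_gte(n, 1e4)
  r <- stats::cor(as.vector(a[, 1, ]), as.vector(a[, 2, ]))
  expect_lt(abs(r - 0.9), 0.03)
})

test_that("under a null config yes and no trials are exchangeable", {
  # single channel so pooled samples are iid and the KS test is exact
  rejections <- 0L
  for (seed in 1:20) {
    cfg <- syntheticConfig(sessionsPerDay = 1, trialsPerCondition = 20,
                           nChannels = 1, epochWindow = c(-2, 10),
                           samplingRate = 2, effectAmplitude = 0, seed = seed)
    s <- allSessions(generateDataset(cfg))[[1]]
    ks <- suppressWarnings(stats::ks.test(as.vector(s@trialsYes),
                                          as.vector(s@trialsNo)))
    if (ks$p.value < 0.05) rejections <- rejections + 1L
  }
  # nominal expectation is 1 of 20; allow up to 4 (P[>4] < 0.004)
  expect_lte(rejections, 4L)
})

test_that("presets encode their documented conditions", {
  nul <- syntheticPreset("null-highcorr", seed = 5)
  expect_identical(nul@effectAmplitude, 0)
  expect_identical(nul@nChannels, 20L)
  expect_identical(nul@sessionsPerDay, 10L)
  expect_identical(c(nul@trialsYes, nul@trialsNo), c(10L, 10L))
  expect_equal(channelCorrelation(nul), 0.95)
  expect_length(timeAxis(nul), 200L)

  imb <- syntheticPreset("imbalanced", seed = 5)
  expect_identical(c(imb@trialsYes, imb@trialsNo), c(7L, 3L))

  expect_error(syntheticPreset("nope"), "null-highcorr.*effect-strong.*imbalanced")
})

test_that("the effect-strong amplitude hits Bayes accuracy ~0.9", {
  # Monte-Carlo likelihood-ratio oracle on the generative model
  acc <- bayesAccuracy(syntheticPreset("effect-strong"), nSim = 10000, seed = 1)
  expect_gte(acc, 0.88)
  expect_lte(acc, 0.92)
})

test_that("bayesAccuracy refuses configs it cannot whiten exactly", {
  cfg <- syntheticConfig(driftAr = 0.5, driftInnovationSd = 0.1)
  expect_error(bayesAccuracy(cfg), "drift-free")
})
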