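test_that("feature specs validate their windows", {
  expect_error(featureSpec(baselineWindow = c(-5, 1)), "end <= 0")
  expect_error(featureSpec(responseWindow = c(-1, 8)), "start >= 0")
  d <- smallRandomDataset(1)
  expect_error(extractFeatures(days(d)[[1]],
                               featureSpec(responseWindow = c(2.99, 3.0)),
                               timeAxis(d)),
               "response window.*no timepoints")
})

test_that("a constant signal with baseline correction gives zero features", {
  d <- onesDataset(nSessions = 2L, nTrials = 3L, nChannels = 4L, nT = 12L)
  d@timeAxis <- seq(-2, by = 0.5, length.out = 12L)
  f <- extractFeatures(days(d)[[1]],
                       featureSpec(baselineWindow = c(-2, 0),
                                   responseWindow = c(0, 4)),
                       d@timeAxis)
  expect_identical(max(abs(f$x)), 0)
  expect_identical(levels(f$y), c("no", "yes"))
  expect_length(f$y, 12L)
})

test_that("noiseless effect features equal the windowed response quadrature", {
  g <- c(1, 0.5, 0)
  cfg <- syntheticConfig(sessionsPerDay = 2, trialsPerCondition = 2,
                         nChannels = 3, channelLoadings = g,
                         epochWindow = c(-4, 12), samplingRate = 2,
                         effectAmplitude = 2, sharedNoiseSd = 0,
                         channelNoiseSd = 0, seed = 1)
  d <- generateDataset(cfg)
  spec <- featureSpec(baselineWindow = c(-4, 0), responseWindow = c(3, 8))
  f <- extractFeatures(days(d)[[1]], spec, timeAxis(d))
  tax <- timeAxis(d)
  hbar <- mean(hrf(tax)[tax >= 3 & tax < 8])   # direct window average of h
  yesRows <- f$x[f$y == "yes", , drop = FALSE]
  for (i in seq_len(nrow(yesRows)))
    expect_equal(yesRows[i, ], 2 * hbar * g, tolerance = 1e-12)
  expect_identical(max(abs(f$x[f$y == "no", ])), 0)
})

test_that("window_mean features have one value per channel", {
  d <- generateDataset(syntheticConfig(sessionsPerDay = 1, trialsPerCondition = 2,
                                       nChannels = 20, epochWindow = c(-5, 20),
                                       samplingRate = 2, seed = 5))
  f <- extractFeatures(days(d)[[1]], featureSpec(), timeAxis(d))
  expect_identical(ncol(f$x), 20L)
  ft <- extractFeatures(days(d)[[1]],
                        featureSpec(representation = "full_timecourse"),
                        timeAxis(d))
  tax <- timeAxis(d)
  expect_identical(ncol(ft$x), 20L * sum(tax >= 3 & tax < 8))
})

test_that("undersampling keeps all minority trials and balances counts", {
  expect_identical(balanceByUndersampling(rep(c("yes", "no"), each = 4), 1), 1:8)
  y <- c(rep("yes", 7), rep("no", 3))
  kept <- balanceByUndersampling(y, seed = 2)
  expect_length(kept, 6L)
  expect_identical(sum(y[kept] == "yes"), 3L)
  expect_true(all(8:10 %in% kept))          # every minority trial kept
  removed <- setdiff(seq_along(y), kept)
  expect_true(all(y[removed] == "yes"))     # removals only from the majority
  expect_error(balanceByUndersampling(rep("yes", 5), 1), "two classes")
})

test_that("each majority subset is kept equally often across seeds", {
  y <- c("yes", "yes", "yes", "yes", "no", "no")   # C(4,2) = 6 subsets
  seen <- table(vapply(1:10000, function(s)
    paste(intersect(balanceByUndersampling(y, s), 1:4), collapse = ","),
    character(1)))
  expect_length(seen, 6L)
  expect_true(all(abs(seen / 10000 - 1 / 6) < 0.02))
})

test_that("the dual coordinate descent SVM matches libsvm where both converge", {
  skip_if_not_installed("e1071")
  set.seed(9)
  n <- 200
  x <- matrix(rnorm(n * 10), n)
  y <- factor(rep(c("no", "yes"), length.out = n), levels = c("no", "yes"))
  x[y == "yes", 1:2] <- x[y == "yes", 1:2] + 1
  fit <- linearSvm(x, y, cost = 1)
  expect_true(fit$converged)
  ref <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
  wRef <- drop(crossprod(ref$SV, ref$coefs))
  cs <- abs(sum(wRef * fit$weights) /
              sqrt(sum(wRef^2) * sum(fit$weights^2)))
  expect_gt(cs, 0.995)
  expect_gt(mean(predict(fit, x) == predict(ref, x)), 0.97)
})

test_that("widely separable features are decoded perfectly in every fold", {
  set.seed(4)
  n <- 100
  y <- rep(c("no", "yes"), each = n / 2)
  x <- matrix(rnorm(n * 5, sd = 0.1), n)
  x[y == "yes", 1] <- x[y == "yes", 1] + 10
  cv <- nestedCv(x, y, classifierConfig(seed = 3))
  expect_identical(cv$accuracy, 1)
  expect_true(all(cv$foldAccuracy == 1))
})

test_that("nested CV is deterministic and balances every training fold", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60)
  y <- c(rep("yes", 40), rep("no", 20))
  cv1 <- nestedCv(x, y, classifierConfig(seed = 5))
  cv2 <- nestedCv(x, y, classifierConfig(seed = 5))
  expect_identical(cv1$k, cv2$k)
  expect_identical(cv1$selectedC, cv2$selectedC)
  for (tab in cv1$trainClassCounts)
    expect_identical(unname(tab["yes"]), unname(tab["no"]))
  expect_identical(cv1$n, 60L)
  expect_identical(cv1$accuracy, cv1$k / cv1$n)
})

test_that("tiny minority classes trigger the stratified fallback warning", {
  set.seed(1)
  x <- matrix(rnorm(24 * 3), 24)
  y <- c(rep("yes", 20), rep("no", 4))
  expect_warning(cv <- nestedCv(x, y, classifierConfig(seed = 1)),
                 "stratified fallback")
  expect_identical(max(cv$folds), 4L)
})

test_that("held-out labels never influence training or model selection", {
  set.seed(6)
  x <- matrix(rnorm(60 * 4), 60)
  y <- factor(rep(c("no", "yes"), 30), levels = c("no", "yes"))
  x[y == "yes", 1] <- x[y == "yes", 1] + 0.8
  cfg <- classifierConfig(seed = 2)
  cv <- nestedCv(x, y, cfg)
  y2 <- y
  test1 <- which(cv$folds == 1)
  y2[test1] <- ifelse(y[test1] == "yes", "no", "yes")  # flip held-out labels

  cv2 <- nestedCv(x, y2, cfg, folds = cv$folds)
  expect_identical(cv2$selectedC[1], cv$selectedC[1])
  expect_identical(cv2$decisionValues[[1]], cv$decisionValues[[1]])
})

test_that("per-day reports carry pooled counts and uncorrected p-values", {
  d <- generateDataset(syntheticConfig(nDays = 1, sessionsPerDay = 2,
                                       trialsPerCondition = 10, nChannels = 4,
                                       epochWindow = c(-2, 10), samplingRate = 2,
                                       effectAmplitude = 0, seed = 9))
  rep <- runOfflineReanalysis(d, config = classifierConfig(seed = 1))
  expect_length(rep$days, 1L)
  e <- rep$days[[1]]
  expect_identical(e$n, 40L)
  expect_identical(rep$meanAccuracy, e$accuracy)
  expect_identical(rep$pooledN, 40L)
  expect_identical(e$pValue, e$pAdjusted)   # uncorrected by default
  expect_equal(e$pValue,
               accuracyBinomialTest(e$k, e$n)@pValue, tolerance = 1e-12)
  expect_identical(rep$correction, "none")
})

test_that("null multi-day datasets are mostly declared non-significant", {
  d <- generateDataset(syntheticConfig(nDays = 5, sessionsPerDay = 2,
                                       trialsPerCondition = 10, nChannels = 6,
                                       epochWindow = c(-2, 10), samplingRate = 2,
                                       effectAmplitude = 0,
                                       sharedNoiseSd = sqrt(0.95),
                                       channelNoiseSd = sqrt(0.05), seed = 12))
  rep <- runOfflineReanalysis(d, config = classifierConfig(seed = 4))
  expect_gte(sum(!vapply(rep$days, `[[`, logical(1), "significant")), 4L)
})

test_that("the imbalanced preset flows through day classification", {
  d <- generateDataset(syntheticPreset("imbalanced", seed = 3))
  entry <- classifyDay(days(d)[[1]], featureSpec(), timeAxis(d),
                       classifierConfig(seed = 3))
  expect_identical(entry$n, 100L)           # 10 sessions x (7 + 3)
  expect_s4_class(entry$chanceTest, "ChanceTestResult")
})
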