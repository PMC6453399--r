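test_that("both averaging orders reproduce the worked arithmetic example", {
  d <- workedExampleDataset()
  ca <- collapseDataset(d, "A-flawed")
  cb <- collapseDataset(d, "B-correct")
  expect_equal(as.vector(ca@yes), c(4, 6))          # channel replicates
  expect_equal(as.vector(cb@yes), c(3, 7))          # session replicates
  expect_equal(ca@grandYes, 5)
  expect_equal(cb@grandYes, 5)
  expect_identical(ca@replicateUnit, "channel")
  expect_identical(cb@replicateUnit, "session")
})

test_that("collapse agrees with a brute-force loop oracle", {
  d <- smallRandomDataset(21, balanced = FALSE, nDays = 2L)
  for (m in c("A-flawed", "B-correct")) {
    got <- collapseDataset(d, m)
    want <- bruteCollapse(d, m)
    expect_equal(got@yes, want$yes, tolerance = 1e-12)
    expect_equal(got@no, want$no, tolerance = 1e-12)
    expect_equal(got@grandYes, colMeans(want$yes), tolerance = 1e-12)
  }
})

test_that("an all-ones dataset collapses to all-one replicate rows", {
  d <- onesDataset()
  for (m in c("A-flawed", "B-correct")) {
    cr <- collapseDataset(d, m)
    expect_true(all(cr@yes == 1) && all(cr@no == 1))
  }
})

test_that("balanced designs give identical grand means for both orders", {
  for (seed in 1:10) {
    d <- smallRandomDataset(seed, balanced = TRUE, nSessions = 1L + seed %% 3)
    ga <- collapseDataset(d, "A-flawed")
    gb <- collapseDataset(d, "B-correct")
    expect_lt(max(abs(ga@grandYes - gb@grandYes)), 1e-12)
    expect_lt(max(abs(ga@grandNo - gb@grandNo)), 1e-12)
  }
})

test_that("a session with no trials in one condition is a named error", {
  d <- generateDataset(syntheticConfig(sessionsPerDay = 2, trialsYes = 2,
                                       trialsNo = 0, nChannels = 2,
                                       epochWindow = c(-1, 1), seed = 1))
  expect_error(collapseDataset(d, "A-flawed"), "session 's1'.*'no'")
  expect_error(collapseDataset(d, "B-correct"), "session 's1'.*'no'")
})

test_that("the pooled t-test matches the closed form and stats::t.test", {
  cr <- methods::new("CollapseResult", method = "B-correct",
                     replicateUnit = "session",
                     yes = matrix(c(1, 2, 3), 3, 1), no = matrix(c(4, 5, 6), 3, 1),
                     grandYes = 2, grandNo = 5, timeAxis = 0)
  tc <- timepointTTest(cr)
  # independent closed form: pooled variance t
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(4, 5, 6))) / 4
  tOracle <- (2 - 5) / sqrt(sp2 * (1 / 3 + 1 / 3))
  pOracle <- 2 * pt(-abs(tOracle), 4)
  expect_lt(abs(tc@statistic - tOracle), 1e-10)
  expect_identical(tc@df, 4)
  expect_lt(abs(tc@p - pOracle), 1e-12)
  expect_equal(tc@p, 0.0213, tolerance = 1e-2)
  # cross-check against the reference implementation
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tc@statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(tc@p, tt$p.value, tolerance = 1e-12)
})

test_that("welch and paired variants match stats::t.test", {
  set.seed(42)
  yes <- matrix(rnorm(5 * 3), 5, 3)
  no <- matrix(rnorm(5 * 3, sd = 2), 5, 3)
  cr <- methods::new("CollapseResult", method = "B-correct",
                     replicateUnit = "session", yes = yes, no = no,
                     grandYes = colMeans(yes), grandNo = colMeans(no),
                     timeAxis = 1:3)
  tw <- timepointTTest(cr, welch = TRUE)
  tp <- timepointTTest(cr, paired = TRUE)
  for (j in 1:3) {
    w <- t.test(yes[, j], no[, j])
    p <- t.test(yes[, j], no[, j], paired = TRUE)
    expect_equal(tw@statistic[j], unname(w$statistic), tolerance = 1e-12)
    expect_equal(tw@p[j], w$p.value, tolerance = 1e-12)
    expect_equal(tw@df[j], unname(w$parameter), tolerance = 1e-12)
    expect_equal(tp@statistic[j], unname(p$statistic), tolerance = 1e-12)
    expect_equal(tp@p[j], p$p.value, tolerance = 1e-12)
  }
})

test_that("identical replicates give t = 0, p = 1 everywhere", {
  m <- matrix(rnorm(8), 4, 2)
  cr <- methods::new("CollapseResult", method = "B-correct",
                     replicateUnit = "session", yes = m, no = m,
                     grandYes = colMeans(m), grandNo = colMeans(m),
                     timeAxis = 1:2)
  tc <- timepointTTest(cr)
  expect_identical(tc@statistic, c(0, 0))
  expect_identical(tc@p, c(1, 1))
})

test_that("zero variance with unequal means flags a degenerate timepoint", {
  cr <- methods::new("CollapseResult", method = "B-correct",
                     replicateUnit = "session",
                     yes = matrix(1, 3, 1), no = matrix(2, 3, 1),
                     grandYes = 1, grandNo = 2, timeAxis = 0)
  expect_warning(tc <- timepointTTest(cr), "zero replicate variance")
  expect_identical(tc@p, 0)
  expect_true(tc@degenerate)
})

test_that("fewer than two replicates per condition is an error", {
  cr <- methods::new("CollapseResult", method = "B-correct",
                     replicateUnit = "session",
                     yes = matrix(1, 1, 1), no = matrix(2, 3, 1),
                     grandYes = 1, grandNo = 2, timeAxis = 0)
  expect_error(timepointTTest(cr), ">= 2 replicates")
})

test_that("degrees of freedom follow the replicate-count law", {
  d <- smallRandomDataset(31, nSessions = 4L, nChannels = 6L)
  ta <- timepointTTest(collapseDataset(d, "A-flawed"))
  tb <- timepointTTest(collapseDataset(d, "B-correct"))
  expect_true(all(ta@df == 2 * (6 - 1)))
  expect_true(all(tb@df == 2 * (4 - 1)))
})

test_that("corrections adjust p upward and masks follow adjusted p", {
  d <- generateDataset(smallNullHighCorr(3))
  cr <- collapseDataset(d, "A-flawed")
  raw <- timepointTTest(cr, alpha = 0.05, correction = "none")
  bon <- timepointTTest(cr, alpha = 0.05, correction = "bonferroni")
  bh <- timepointTTest(cr, alpha = 0.05, correction = "bh-fdr")
  expect_true(all(bon@pAdjusted >= raw@p - 1e-15))
  expect_true(all(bh@pAdjusted >= raw@p - 1e-15))
  expect_identical(bon@mask, bon@pAdjusted < 0.05)
  expect_lte(sum(bon@mask), sum(raw@mask))
})

test_that("channelwise tests equal the B-correct collapse for one channel", {
  d <- smallRandomDataset(17, nChannels = 1L)
  cw <- channelwiseTTest(d)
  expect_length(cw, 1L)
  tb <- timepointTTest(collapseDataset(d, "B-correct"))
  expect_equal(cw[[1]]@statistic, tb@statistic, tolerance = 1e-12)
  expect_equal(cw[[1]]@p, tb@p, tolerance = 1e-12)
})

test_that("channelwise analysis returns one curve per channel", {
  d <- generateDataset(syntheticConfig(sessionsPerDay = 2, trialsPerCondition = 2,
                                       nChannels = 20, epochWindow = c(-1, 2),
                                       seed = 2))
  cw <- channelwiseTTest(d)
  expect_length(cw, 20L)
  expect_named(cw, sprintf("channel%d", 0:19))
  expect_true(all(vapply(cw, function(x) x@replicateUnit, character(1)) == "session"))
})

test_that("identical yes/no data give p = 1 on every channel", {
  d <- onesDataset(nSessions = 3L, nChannels = 3L)
  cw <- channelwiseTTest(d)
  for (tc in cw) expect_true(all(tc@p == 1))
})

test_that("the flawed order inflates the false-positive rate; the correct one does not", {
  fracA <- fracB <- numeric(5)
  for (s in 1:5) {
    d <- generateDataset(smallNullHighCorr(s))
    fracA[s] <- mean(timepointTTest(collapseDataset(d, "A-flawed"))@p < 0.05)
    fracB[s] <- mean(timepointTTest(collapseDataset(d, "B-correct"))@p < 0.05)
  }
  expect_gt(mean(fracA), 0.3)
  expect_lt(mean(fracB), 0.15)
})

test_that("under the correct order null p-values are uniform", {
  passes <- 0L
  for (rep in 1:20) {
    d <- generateDataset(smallNullHighCorr(100 + rep, nSessions = 6L,
                                           nTrials = 4L, nChannels = 4L))
    p <- timepointTTest(collapseDataset(d, "B-correct"))@p
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    if (ks$p.value >= 0.01) passes <- passes + 1L
  }
  expect_gte(passes, 18L)
})

test_that("compareMethods composes both orders and counts significance", {
  d <- onesDataset()
  cmp <- compareMethods(d)
  expect_identical(cmp$nSigA, 0L)
  expect_identical(cmp$nSigB, 0L)
  expect_lt(max(abs(cmp$collapseA@grandYes - cmp$collapseB@grandYes)), 1e-12)

  d2 <- generateDataset(smallNullHighCorr(1))
  cmp2 <- compareMethods(d2)
  expect_gt(cmp2$nSigA, cmp2$nSigB)
})
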