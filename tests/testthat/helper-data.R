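# Fixtures are built in code; nothing is read from disk.

# the worked 2 sessions x 2 trials x 2 channels x 1 timepoint example:
# yes-values s1: trials (1,3), (3,5); s2: (5,7), (7,9); no-values all zero
workedExampleDataset <- function() {
  mk <- function(vals) array(vals, c(2L, 2L, 1L))   # trial x channel x time
  s1 <- SessionRecord("s1", mk(c(1, 3, 3, 5)), mk(rep(0, 4)))
  s2 <- SessionRecord("s2", mk(c(5, 7, 7, 9)), mk(rep(0, 4)))
  TrialDataset("worked", list(DayRecord("d1", list(s1, s2))),
               timeAxis = 0, samplingRate = 1)
}

onesDataset <- function(nSessions = 2L, nTrials = 2L, nChannels = 2L,
                        nT = 4L) {
  sess <- lapply(seq_len(nSessions), function(i)
    SessionRecord(sprintf("s%d", i),
                  array(1, c(nTrials, nChannels, nT)),
                  array(1, c(nTrials, nChannels, nT))))
  TrialDataset("ones", list(DayRecord("d1", sess)),
               timeAxis = seq(0, by = 0.5, length.out = nT),
               samplingRate = 2)
}

# small random valid dataset; balanced = equal trials per condition
smallRandomDataset <- function(seed, balanced = TRUE, nDays = 1L,
                               nSessions = 3L, nTrials = 3L,
                               nChannels = 4L) {
  generateDataset(syntheticConfig(
    nDays = nDays, sessionsPerDay = nSessions,
    trialsYes = nTrials, trialsNo = if (balanced) nTrials else nTrials + 2L,
    nChannels = nChannels, epochWindow = c(-2, 3), samplingRate = 2,
    effectAmplitude = 0.5, sharedNoiseSd = 1, channelNoiseSd = 0.5,
    seed = seed))
}

# a compact highly correlated null configuration for separation checks
# (same noise structure as the null-highcorr preset, smaller everywhere)
smallNullHighCorr <- function(seed, nSessions = 8L, nTrials = 6L,
                              nChannels = 10L) {
  syntheticConfig(nDays = 1L, sessionsPerDay = nSessions,
                  trialsPerCondition = nTrials, nChannels = nChannels,
                  epochWindow = c(-2, 10.5), samplingRate = 4,  # 50 timepoints
                  effectAmplitude = 0, sharedNoiseSd = sqrt(0.95),
                  channelNoiseSd = sqrt(0.05), seed = seed)
}

# collapse a session list by brute-force loops (independent oracle)
bruteCollapse <- function(dataset, method) {
  sess <- allSessions(dataset)
  nT <- length(timeAxis(dataset))
  C <- nChannels(dataset)
  get <- function(s, cond) if (cond == "yes") s@trialsYes else s@trialsNo
  out <- list()
  for (cond in c("yes", "no")) {
    if (method == "A-flawed") {
      rows <- matrix(0, C, nT)
      for (ch in seq_len(C)) for (tp in seq_len(nT)) {
        perSession <- sapply(sess, function(s) {
          a <- get(s, cond)
          mean(sapply(seq_len(dim(a)[1]), function(tr) a[tr, ch, tp]))
        })
        rows[ch, tp] <- mean(perSession)
      }
    } else {
      rows <- matrix(0, length(sess), nT)
      for (si in seq_along(sess)) for (tp in seq_len(nT)) {
        a <- get(sess[[si]], cond)
        perTrial <- sapply(seq_len(dim(a)[1]), function(tr)
          mean(sapply(seq_len(C), function(ch) a[tr, ch, tp])))
        rows[si, tp] <- mean(perTrial)
      }
    }
    out[[cond]] <- rows
  }
  out
}
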