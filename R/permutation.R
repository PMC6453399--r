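#' @include AllClasses.R averaging.R
NULL

# ---------------------------------------------------------------------------
# Permutation validity audit: rerun a statistical procedure with condition
# labels randomly reassigned. A sound procedure should then find nothing;
# a procedure that keeps "discovering" effects in permuted labels is
# anticonservative, whatever it reports on the real labels.
# ---------------------------------------------------------------------------

#' Randomly permute condition labels of a trial dataset
#'
#' Reassigns trials to the "yes"/"no" conditions at random while leaving
#' every signal value untouched. The default scope is within-session:
#' each session's pooled trials are reshuffled preserving that session's
#' original per-condition counts (the conservative,
#' exchangeability-respecting choice). `scope = "global"` shuffles trials
#' across all sessions (sessions keep their per-condition counts but may
#' receive trials recorded elsewhere). Deterministic given `seed`.
#'
#' @param dataset a valid [TrialDataset-class].
#' @param seed integer seed.
#' @param scope `"session"` (default) or `"global"`.
#' @return a [TrialDataset-class] with permuted labels.
#' @export
permuteLabels <- function(dataset, seed, scope = c("session", "global")) {
  scope <- match.arg(scope)
  nT <- length(dataset@timeAxis)
  C <- dataset@nChannels
  pool <- function(s) {
    nY <- dim(s@trialsYes)[1L]; nN <- dim(s@trialsNo)[1L]
    arr <- array(0, c(nY + nN, C, nT))
    if (nY) arr[seq_len(nY), , ] <- s@trialsYes
    if (nN) arr[nY + seq_len(nN), , ] <- s@trialsNo
    arr
  }
  rebuild <- function(s, arr, sel) {
    n <- dim(arr)[1L]
    SessionRecord(s@sessionId,
                  arr[sel, , , drop = FALSE],
                  arr[setdiff(seq_len(n), sel), , , drop = FALSE])
  }
  if (scope == "session") {
    counter <- 0L
    newDays <- lapply(dataset@days, function(d) {
      newSess <- lapply(d@sessions, function(s) {
        counter <<- counter + 1L
        arr <- pool(s)
        nY <- dim(s@trialsYes)[1L]
        n <- dim(arr)[1L]
        sel <- if (nY == 0L || nY == n) seq_len(nY) else
          withSeed(deriveSeed(seed, counter), sort(sample.int(n, nY)))
        rebuild(s, arr, sel)
      })
      DayRecord(d@dayId, newSess)
    })
  } else {
    sess <- allSessions(dataset)
    arrs <- lapply(sess, pool)
    sizes <- vapply(arrs, function(a) dim(a)[1L], integer(1))
    total <- sum(sizes)
    big <- array(0, c(total, C, nT))
    off <- 0L
    for (a in arrs) {
      if (dim(a)[1L]) big[off + seq_len(dim(a)[1L]), , ] <- a
      off <- off + dim(a)[1L]
    }
    perm <- withSeed(deriveSeed(seed, 0L), sample.int(total))
    off <- 0L; si <- 0L
    newDays <- lapply(dataset@days, function(d) {
      newSess <- lapply(d@sessions, function(s) {
        si <<- si + 1L
        n <- sizes[si]
        take <- perm[off + seq_len(n)]
        off <<- off + n
        nY <- dim(s@trialsYes)[1L]
        sub <- big[take, , , drop = FALSE]
        rebuild(s, sub, seq_len(nY))
      })
      DayRecord(d@dayId, newSess)
    })
  }
  TrialDataset(dataset@patientId, newDays, dataset@timeAxis,
               dataset@samplingRate, nChannels = C)
}

#' Permutation validity audit of an averaging-order procedure
#'
#' Repeats, for `nPerm` random label permutations: [permuteLabels()] ->
#' [collapseDataset()] under `method` -> [timepointTTest()], and flags a
#' permutation if any timepoint has uncorrected p below `auditAlpha`. A
#' correct procedure flags permutations at roughly the rate expected from
#' the number of (effectively independent) timepoints; an anticonservative
#' one flags essentially all of them. Per-permutation seeds are derived
#' from the master seed and the permutation index, so results are
#' reproducible and permutations independent.
#'
#' @param dataset a valid [TrialDataset-class].
#' @param method `"A-flawed"` or `"B-correct"`.
#' @param nPerm number of permutations (>= 0).
#' @param auditAlpha per-timepoint threshold defining a "significant"
#'   permutation (default 0.0005, the display threshold conventionally
#'   used for the flawed method's masks).
#' @param seed master integer seed.
#' @param scope permutation scope, see [permuteLabels()].
#' @return an object of class `"permutationAudit"`: list with
#'   `nPermutations`, per-permutation `significantCounts` and `flagged`,
#'   `fractionFlagged`, `auditAlpha`, `method`, `scope`, `seed`.
#' @examples
#' d <- generateDataset(syntheticConfig(sessionsPerDay = 4,
#'   trialsPerCondition = 4, nChannels = 6, sharedNoiseSd = 3,
#'   channelNoiseSd = 1, seed = 2))
#' permutationAudit(d, "A-flawed", nPerm = 3, seed = 9)
#' @export
permutationAudit <- function(dataset, method = c("B-correct", "A-flawed"),
                             nPerm = 10L, auditAlpha = 5e-4, seed = 1L,
                             scope = c("session", "global")) {
  method <- .matchMethod(method)
  scope <- match.arg(scope)
  if (nPerm < 0L) stopf("nPerm must be >= 0")
  counts <- integer(nPerm)
  for (i in seq_len(nPerm)) {
    perm <- permuteLabels(dataset, deriveSeed(seed, i), scope = scope)
    tc <- timepointTTest(collapseDataset(perm, method),
                         alpha = auditAlpha, correction = "none")
    counts[i] <- sum(tc@p < auditAlpha)
  }
  flagged <- counts > 0L
  structure(list(nPermutations = as.integer(nPerm),
                 significantCounts = counts, flagged = flagged,
                 fractionFlagged = if (nPerm > 0L) mean(flagged) else 0,
                 auditAlpha = auditAlpha, method = method, scope = scope,
                 seed = as.integer(seed)),
            class = "permutationAudit")
}

#' @export
print.permutationAudit <- function(x, ...) {
  cat(sprintf(paste0(
    "Permutation validity audit (%s, %s scope, audit alpha = %g)\n",
    "  %d / %d permutations show >= 1 significant timepoint (fraction %.2f)\n"),
    x$method, x$scope, x$auditAlpha,
    sum(x$flagged), x$nPermutations, x$fractionFlagged))
  if (x$nPermutations > 0L)
    cat("  significant-timepoint counts:",
        paste(x$significantCounts, collapse = " "), "\n")
  invisible(x)
}
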