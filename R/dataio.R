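#' @include AllClasses.R
NULL

# Interchange format: a JSON manifest holding the structure and the
# authoritative time axis, plus one tidy long CSV per session with header
# condition,trial,channel,time_s,value. Trial and channel indices are
# 0-based and contiguous; condition is "yes" or "no".

#' List invariant violations of a TrialDataset
#'
#' Checks every dataset invariant (consistent channel/timepoint counts,
#' strictly increasing uniform time axis consistent with the sampling
#' rate, finite signal values, day/session structure) and returns a
#' character vector of human-readable violations, each naming the
#' day/session/condition/trial where the problem sits. An empty vector
#' means the dataset is valid. Violations are returned, never raised.
#'
#' @param dataset a [TrialDataset-class] (possibly malformed).
#' @return character vector of violation descriptions (empty if valid).
#' @examples
#' d <- generateDataset(syntheticConfig(sessionsPerDay = 1,
#'   trialsPerCondition = 2, nChannels = 2, seed = 1))
#' validateDataset(d)  # character(0)
#' @export
validateDataset <- function(dataset) {
  v <- character()
  if (length(dataset@patientId) != 1L || !nzchar(dataset@patientId))
    v <- c(v, "patientId must be a single non-empty string")
  if (dataset@nChannels < 1L)
    v <- c(v, "nChannels must be a positive integer")
  tax <- dataset@timeAxis
  nT <- length(tax)
  if (nT < 1L) v <- c(v, "timeAxis must be non-empty")
  if (nT >= 2L) {
    dt <- diff(tax)
    if (any(dt <= 0)) v <- c(v, "timeAxis must be strictly increasing")
    else {
      step <- mean(dt)
      if (any(abs(dt - step) > 1e-9 * max(1, abs(step))))
        v <- c(v, "timeAxis spacing is not uniform (relative tolerance 1e-9)")
      if (!relClose(step, 1 / dataset@samplingRate))
        v <- c(v, sprintf("timeAxis spacing %.12g is inconsistent with samplingRate %g Hz",
                          step, dataset@samplingRate))
    }
  }
  if (!length(dataset@days)) v <- c(v, "dataset has no days")
  dayIds <- vapply(dataset@days, function(d) d@dayId, character(1))
  if (anyDuplicated(dayIds))
    v <- c(v, sprintf("duplicated day ids: %s",
                      paste(unique(dayIds[duplicated(dayIds)]), collapse = ", ")))
  for (d in dataset@days) {
    if (!length(d@sessions))
      v <- c(v, sprintf("day '%s' has no sessions", d@dayId))
    sesIds <- vapply(d@sessions, function(s) s@sessionId, character(1))
    if (anyDuplicated(sesIds))
      v <- c(v, sprintf("day '%s': duplicated session ids", d@dayId))
    for (s in d@sessions) {
      for (cond in c("yes", "no")) {
        arr <- if (cond == "yes") s@trialsYes else s@trialsNo
        where <- sprintf("day '%s' / session '%s' / %s", d@dayId, s@sessionId, cond)
        dm <- dim(arr)
        if (length(dm) != 3L) {
          v <- c(v, sprintf("%s: trial tensor is not 3-dimensional", where))
          next
        }
        if (dm[2L] != dataset@nChannels)
          v <- c(v, sprintf("%s: %d channels, expected %d", where, dm[2L],
                            dataset@nChannels))
        if (dm[3L] != nT)
          v <- c(v, sprintf("%s: %d timepoints, expected %d", where, dm[3L], nT))
        if (dm[1L] > 0L && !all(is.finite(arr))) {
          bad <- which(apply(!is.finite(arr), 1L, any))
          for (tr in bad)
            v <- c(v, sprintf("%s / trial %d: non-finite signal value", where, tr - 1L))
        }
      }
    }
  }
  v
}

.csvHeader <- c("condition", "trial", "channel", "time_s", "value")

.sessionToTable <- function(session, timeAxis) {
  one <- function(arr, cond) {
    n <- dim(arr)[1L]; C <- dim(arr)[2L]; nT <- dim(arr)[3L]
    if (n == 0L) return(NULL)
    # as.vector(arr) runs trial fastest, then channel, then time
    data.table::data.table(
      condition = cond,
      trial = rep(seq_len(n) - 1L, times = C * nT),
      channel = rep(rep(seq_len(C) - 1L, each = n), times = nT),
      time_s = rep(timeAxis, each = n * C),
      value = as.vector(arr))
  }
  out <- data.table::rbindlist(
    list(one(session@trialsYes, "yes"), one(session@trialsNo, "no")))
  if (nrow(out)) data.table::setorderv(out, c("condition", "trial", "channel", "time_s"),
                                       order = c(-1L, 1L, 1L, 1L))
  out
}

#' Write a TrialDataset to a manifest + per-session CSV directory
#'
#' Emits `manifest.json` (structure plus the authoritative time axis) and
#' one long-format CSV per session with header
#' `condition,trial,channel,time_s,value`. The output is exactly
#' re-readable by [readDataset()]; round-tripping reproduces every signal
#' value to better than 1e-12.
#'
#' @param dataset a valid [TrialDataset-class].
#' @param outDir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(dataset, outDir) {
  methods::validObject(dataset)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", outDir)
  sessionsJson <- list()
  daysJson <- vector("list", length(dataset@days))
  for (i in seq_along(dataset@days)) {
    d <- dataset@days[[i]]
    sess <- vector("list", length(d@sessions))
    for (j in seq_along(d@sessions)) {
      s <- d@sessions[[j]]
      fname <- sprintf("%s_%s.csv",
                       gsub("[^A-Za-z0-9_.-]", "-", d@dayId),
                       gsub("[^A-Za-z0-9_.-]", "-", s@sessionId))
      tab <- .sessionToTable(s, dataset@timeAxis)
      if (is.null(tab) || !nrow(tab))
        tab <- data.table::setnames(
          data.table::data.table(character(), integer(), integer(),
                                 numeric(), numeric()), .csvHeader)
      data.table::fwrite(tab, file.path(outDir, fname))
      sess[[j]] <- list(session_id = s@sessionId, csv = fname)
    }
    daysJson[[i]] <- list(day_id = d@dayId, sessions = sess)
  }
  manifest <- list(patient_id = dataset@patientId,
                   n_channels = dataset@nChannels,
                   sampling_rate_hz = dataset@samplingRate,
                   time_axis_s = dataset@timeAxis,
                   days = daysJson)
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.readSessionCsv <- function(path, sessionId, nChannels, timeAxis) {
  if (!file.exists(path))
    stopf("I/O error: session CSV '%s' does not exist", path)
  tab <- data.table::fread(path, header = TRUE, sep = ",",
                           colClasses = list(character = "condition"))
  if (!identical(names(tab), .csvHeader))
    stopf("validation error in '%s': header must be exactly '%s' (got '%s')",
          path, paste(.csvHeader, collapse = ","),
          paste(names(tab), collapse = ","))
  nT <- length(timeAxis)
  readCond <- function(cond) {
    rows <- which(tab$condition == cond)
    if (!length(rows)) return(array(numeric(), c(0L, nChannels, nT)))
    sub <- tab[rows]
    ids <- sort(unique(sub$trial))
    n <- length(ids)
    if (!identical(as.integer(ids), seq_len(n) - 1L))
      stopf("validation error in '%s' (%s): trial indices must be 0-based and contiguous, got {%s}",
            path, cond, paste(ids, collapse = ","))
    if (nrow(sub) != n * nChannels * nT)
      stopf("validation error in '%s' (%s): %d rows, expected %d (ragged trials?)",
            path, cond, nrow(sub), n * nChannels * nT)
    if (any(sub$channel < 0L | sub$channel >= nChannels))
      stopf("validation error in '%s' (%s): channel index outside 0..%d",
            path, cond, nChannels - 1L)
    tIdx <- round((sub$time_s - timeAxis[1]) * (nT - 1) /
                    (timeAxis[nT] - timeAxis[1])) + 1L
    if (nT == 1L) tIdx <- rep(1L, nrow(sub))
    badT <- which(tIdx < 1L | tIdx > nT |
                    abs(timeAxis[pmax(pmin(tIdx, nT), 1L)] - sub$time_s) > 1e-9)
    if (length(badT))
      stopf("validation error in '%s' (%s), row %d: time_s = %.12g does not match the manifest time axis within 1e-9 s",
            path, cond, rows[badT[1]] + 1L, sub$time_s[badT[1]])
    badV <- which(!is.finite(sub$value))
    if (length(badV))
      stopf("validation error in '%s' (%s), row %d: non-finite value",
            path, cond, rows[badV[1]] + 1L)
    arr <- array(NA_real_, c(n, nChannels, nT))
    arr[cbind(sub$trial + 1L, sub$channel + 1L, tIdx)] <- sub$value
    miss <- which(is.na(arr), arr.ind = TRUE)
    if (nrow(miss))
      stopf("validation error in '%s' (%s): missing sample for trial %d, channel %d, timepoint %d",
            path, cond, miss[1, 1] - 1L, miss[1, 2] - 1L, miss[1, 3])
    arr
  }
  bad <- setdiff(unique(tab$condition), c("yes", "no"))
  if (length(bad)) {
    row <- which(tab$condition == bad[1])[1]
    stopf("validation error in '%s', row %d: unknown condition label '%s' (must be 'yes' or 'no')",
          path, row + 1L, bad[1])
  }
  SessionRecord(sessionId, readCond("yes"), readCond("no"))
}

#' Read a TrialDataset from a manifest
#'
#' Reads the JSON manifest written by [writeDataset()] (or assembled by
#' hand to the same schema), loads every referenced session CSV, checks
#' the schema (condition labels, contiguous 0-based trial indices, time
#' axis agreement within 1e-9 s, finite values) and returns a validated
#' [TrialDataset-class]. Schema violations raise errors naming the file
#' and row; missing files raise I/O errors naming the path.
#'
#' @param manifestPath path to `manifest.json`.
#' @return a validated [TrialDataset-class].
#' @seealso [writeDataset()], [validateDataset()]
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stopf("I/O error: manifest '%s' does not exist", manifestPath)
  m <- jsonlite::fromJSON(manifestPath, simplifyVector = FALSE)
  need <- c("patient_id", "n_channels", "sampling_rate_hz", "time_axis_s", "days")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stopf("validation error in '%s': manifest missing field(s) %s",
          manifestPath, paste(miss, collapse = ", "))
  tax <- as.numeric(unlist(m$time_axis_s))
  nCh <- as.integer(m$n_channels)
  base <- dirname(manifestPath)
  daysList <- lapply(m$days, function(d) {
    sess <- lapply(d$sessions, function(s)
      .readSessionCsv(file.path(base, s$csv), s$session_id, nCh, tax))
    DayRecord(d$day_id, sess)
  })
  TrialDataset(m$patient_id, daysList, tax, as.numeric(m$sampling_rate_hz),
               nChannels = nCh)
}
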