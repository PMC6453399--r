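#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Accessors and show methods for the core data model
# ---------------------------------------------------------------------------

#' Accessors for TrialDataset and friends
#'
#' `patientId`, `days`, `nChannels`, `timeAxis`, `samplingRate` read the
#' corresponding dataset slots; `sessions` lists a day's sessions;
#' `trials` extracts one session's trial tensor for a condition;
#' `allSessions` flattens the day/session hierarchy in order.
#'
#' @param x a [TrialDataset-class], [DayRecord-class] or
#'   [SessionRecord-class] as appropriate.
#' @param condition `"yes"` or `"no"`.
#' @return the slot value; for `trials` a `[trial, channel, timepoint]`
#'   array; for `allSessions` a list of [SessionRecord-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "TrialDataset", function(x) x@patientId)

#' @rdname accessors
#' @export
setGeneric("days", function(x) standardGeneric("days"))
#' @rdname accessors
#' @export
setMethod("days", "TrialDataset", function(x) x@days)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "TrialDataset", function(x) x@nChannels)

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setMethod("timeAxis", "TrialDataset", function(x) x@timeAxis)
#' @rdname accessors
#' @export
setMethod("timeAxis", "SyntheticConfig", function(x) {
  nT <- floor((x@epochWindow[2] - x@epochWindow[1]) * x@samplingRate + 1e-9)
  seq(x@epochWindow[1], by = 1 / x@samplingRate, length.out = nT)
})

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "TrialDataset", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))
#' @rdname accessors
#' @export
setMethod("sessions", "DayRecord", function(x) x@sessions)

#' @rdname accessors
#' @export
setGeneric("trials", function(x, condition) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "SessionRecord", function(x, condition) {
  condition <- match.arg(condition, c("yes", "no"))
  if (condition == "yes") x@trialsYes else x@trialsNo
})

#' @rdname accessors
#' @export
allSessions <- function(x) {
  unlist(lapply(x@days, function(d) d@sessions), recursive = FALSE)
}

# total trial count of a day, both conditions
dayTrialCount <- function(day) {
  sum(vapply(day@sessions,
             function(s) dim(s@trialsYes)[1L] + dim(s@trialsNo)[1L],
             integer(1)))
}

setMethod("show", "SessionRecord", function(object) {
  cat(sprintf("SessionRecord '%s': %d yes / %d no trials\n",
              object@sessionId, dim(object@trialsYes)[1L],
              dim(object@trialsNo)[1L]))
})

setMethod("show", "DayRecord", function(object) {
  cat(sprintf("DayRecord '%s': %d session(s)\n",
              object@dayId, length(object@sessions)))
})

setMethod("show", "TrialDataset", function(object) {
  ss <- allSessions(object)
  nyes <- sum(vapply(ss, function(s) dim(s@trialsYes)[1L], integer(1)))
  nno <- sum(vapply(ss, function(s) dim(s@trialsNo)[1L], integer(1)))
  cat(sprintf(paste0(
    "TrialDataset patient '%s'\n",
    "  %d day(s), %d session(s); %d yes / %d no trials\n",
    "  %d channels x %d timepoints (%.3g s to %.3g s at %g Hz)\n"),
    object@patientId, length(object@days), length(ss), nyes, nno,
    object@nChannels, length(object@timeAxis),
    object@timeAxis[1], object@timeAxis[length(object@timeAxis)],
    object@samplingRate))
})

setMethod("show", "CollapseResult", function(object) {
  cat(sprintf(paste0(
    "CollapseResult (method %s)\n",
    "  replicate unit: %s (%d yes / %d no rows) x %d timepoints\n"),
    object@method, object@replicateUnit,
    nrow(object@yes), nrow(object@no), ncol(object@yes)))
})

setMethod("show", "TestCurve", function(object) {
  cat(sprintf(paste0(
    "TestCurve over %d timepoints (replicate unit: %s)\n",
    "  alpha = %g, correction = %s: %d significant timepoint(s)\n"),
    length(object@statistic), object@replicateUnit, object@alpha,
    object@correction, sum(object@mask)))
  if (any(object@degenerate))
    cat(sprintf("  warning: %d timepoint(s) with zero replicate variance and unequal means\n",
                sum(object@degenerate)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0(
    "SyntheticConfig: %d day(s) x %d session(s) x (%d yes + %d no) trials\n",
    "  %d channels, epoch [%g, %g) s at %g Hz (%d timepoints)\n",
    "  beta = %g, sigma_shared = %.4g, sigma_chan = %.4g, phi = %g (rho = %.3f)\n",
    "  seed = %d\n"),
    object@nDays, object@sessionsPerDay, object@trialsYes, object@trialsNo,
    object@nChannels, object@epochWindow[1], object@epochWindow[2],
    object@samplingRate, length(timeAxis(object)),
    object@effectAmplitude, object@sharedNoiseSd, object@channelNoiseSd,
    object@driftAr, channelCorrelation(object), object@seed))
})

setMethod("show", "ChanceTestResult", function(object) {
  cat(sprintf(paste0(
    "Exact binomial test vs chance = %g (%s)\n",
    "  accuracy %d/%d = %.3f, p = %.5g [%ssignificant at alpha = %g]\n",
    "  %g%% Clopper-Pearson CI: [%.3f, %.3f]\n"),
    object@chance, object@alternative, object@k, object@n,
    object@k / object@n, object@pValue,
    if (object@significant) "" else "not ", object@alpha,
    100 * (1 - object@alpha), object@ci[1], object@ci[2]))
})
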