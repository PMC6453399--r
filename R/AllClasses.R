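#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# Core data model: patient -> days -> sessions -> per-condition trial tensors
# ---------------------------------------------------------------------------

#' SessionRecord: one recording session's trials
#'
#' Holds the per-condition trial tensors of a single session. Each tensor
#' is a 3-d array `[trial, channel, timepoint]` of preprocessed relative
#' HbO change (dimensionless). A condition may have zero trials; the two
#' conditions may have unequal trial counts.
#'
#' @slot sessionId character label, unique within its day.
#' @slot trialsYes numeric array `[trial, channel, timepoint]` for "yes" trials.
#' @slot trialsNo numeric array `[trial, channel, timepoint]` for "no" trials.
#' @exportClass SessionRecord
setClass("SessionRecord",
  representation(sessionId = "character",
                 trialsYes = "array",
                 trialsNo  = "array"))

#' Construct a SessionRecord
#'
#' @param sessionId session label.
#' @param trialsYes,trialsNo numeric arrays `[trial, channel, timepoint]`.
#' @return a [SessionRecord-class] object.
#' @export
SessionRecord <- function(sessionId, trialsYes, trialsNo) {
  methods::new("SessionRecord", sessionId = as.character(sessionId),
               trialsYes = trialsYes, trialsNo = trialsNo)
}

#' DayRecord: one day's sessions
#'
#' The per-day grouping is the unit over which offline classification is
#' run (one cross-validated decoder per day).
#'
#' @slot dayId character label, unique within the dataset.
#' @slot sessions list of [SessionRecord-class], at least one.
#' @exportClass DayRecord
setClass("DayRecord",
  representation(dayId = "character", sessions = "list"))

#' Construct a DayRecord
#' @param dayId day label.
#' @param sessions list of [SessionRecord-class].
#' @return a [DayRecord-class] object.
#' @export
DayRecord <- function(dayId, sessions) {
  methods::new("DayRecord", dayId = as.character(dayId), sessions = sessions)
}

#' TrialDataset: a patient's full trial-structured recording
#'
#' Container for a multichannel trial dataset organized as
#' patient -> day -> session -> condition ("yes"/"no") -> trials. All
#' trial tensors share one channel count and one time axis (seconds
#' relative to stimulus onset, uniformly spaced, consistent with the
#' sampling rate). Constructed objects are validated; use
#' [validateDataset()] to list violations without raising.
#'
#' @slot patientId character label.
#' @slot days ordered list of [DayRecord-class].
#' @slot nChannels integer channel count shared by all trials.
#' @slot timeAxis numeric vector of seconds relative to onset.
#' @slot samplingRate sampling rate in Hz.
#' @seealso [readDataset()], [writeDataset()], [generateDataset()]
#' @exportClass TrialDataset
setClass("TrialDataset",
  representation(patientId = "character",
                 days = "list",
                 nChannels = "integer",
                 timeAxis = "numeric",
                 samplingRate = "numeric"))

#' Construct a TrialDataset
#'
#' @param patientId patient label.
#' @param days list of [DayRecord-class].
#' @param timeAxis numeric vector of seconds relative to onset.
#' @param samplingRate sampling rate in Hz.
#' @param nChannels channel count; inferred from the first session when omitted.
#' @return a validated [TrialDataset-class] object.
#' @export
TrialDataset <- function(patientId, days, timeAxis, samplingRate,
                         nChannels = NULL) {
  if (is.null(nChannels)) {
    nChannels <- NA_integer_
    for (d in days) for (s in d@sessions) {
      for (arr in list(s@trialsYes, s@trialsNo)) {
        if (length(dim(arr)) == 3L) { nChannels <- dim(arr)[2L]; break }
      }
      if (!is.na(nChannels)) break
    }
    if (is.na(nChannels))
      stopf("cannot infer nChannels: no session with a 3-d trial tensor")
  }
  methods::new("TrialDataset", patientId = as.character(patientId),
               days = days, nChannels = as.integer(nChannels),
               timeAxis = as.numeric(timeAxis),
               samplingRate = as.numeric(samplingRate))
}

setValidity("TrialDataset", function(object) {
  v <- validateDataset(object)
  if (length(v)) v else TRUE
})

# ---------------------------------------------------------------------------
# Averaging results
# ---------------------------------------------------------------------------

#' CollapseResult: replicate-by-timepoint matrices after an averaging order
#'
#' Result of collapsing two of the three axes (trial, session, channel) of
#' a [TrialDataset-class] by stagewise unweighted means, leaving one
#' replicate axis whose across-unit variance a subsequent t-test uses.
#'
#' @slot method `"A-flawed"` (collapse trials then sessions; channel
#'   replicates) or `"B-correct"` (collapse channels then trials; session
#'   replicates).
#' @slot replicateUnit `"channel"` or `"session"`.
#' @slot yes,no numeric matrices `[replicate unit, timepoint]`.
#' @slot grandYes,grandNo per-condition grand-mean curves (mean over units).
#' @slot timeAxis seconds relative to onset.
#' @seealso [collapseDataset()], [timepointTTest()]
#' @exportClass CollapseResult
setClass("CollapseResult",
  representation(method = "character", replicateUnit = "character",
                 yes = "matrix", no = "matrix",
                 grandYes = "numeric", grandNo = "numeric",
                 timeAxis = "numeric"))

#' TestCurve: timepoint-wise t statistics with significance mask
#'
#' @slot statistic t statistic per timepoint (yes minus no).
#' @slot df degrees of freedom per timepoint.
#' @slot p two-sided p-value per timepoint.
#' @slot pAdjusted p after the requested multiple-comparison correction.
#' @slot alpha significance level used for the mask.
#' @slot correction `"none"`, `"bonferroni"`, or `"bh-fdr"`.
#' @slot mask logical, `pAdjusted < alpha`.
#' @slot degenerate logical per timepoint: zero replicate variance with
#'   unequal means (p forced to 0; flagged, not an error).
#' @slot replicateUnit axis supplying the variance.
#' @exportClass TestCurve
setClass("TestCurve",
  representation(statistic = "numeric", df = "numeric", p = "numeric",
                 pAdjusted = "numeric", alpha = "numeric",
                 correction = "character", mask = "logical",
                 degenerate = "logical", replicateUnit = "character"))

# ---------------------------------------------------------------------------
# Synthetic generator configuration
# ---------------------------------------------------------------------------

#' HRFParams: canonical double-gamma hemodynamic response parameters
#'
#' @slot peakDelay,undershootDelay gamma peak locations in seconds (defaults 6, 16).
#' @slot peakDispersion,undershootDispersion gamma dispersions in seconds (defaults 1, 1).
#' @slot undershootRatio relative undershoot amplitude (default 1/6).
#' @seealso [hrf()]
#' @exportClass HRFParams
setClass("HRFParams",
  representation(peakDelay = "numeric", undershootDelay = "numeric",
                 peakDispersion = "numeric", undershootDispersion = "numeric",
                 undershootRatio = "numeric"))

setValidity("HRFParams", function(object) {
  v <- character()
  if (object@peakDelay <= 0 || object@undershootDelay <= 0)
    v <- c(v, "HRF delays must be > 0")
  if (object@peakDispersion <= 0 || object@undershootDispersion <= 0)
    v <- c(v, "HRF dispersions must be > 0")
  if (object@undershootRatio < 0)
    v <- c(v, "HRF undershoot ratio must be >= 0")
  if (length(v)) v else TRUE
})

#' Construct HRF parameters
#'
#' Defaults give the canonical double-gamma response peaking near 5 s.
#'
#' @param peakDelay,undershootDelay,peakDispersion,undershootDispersion,undershootRatio
#'   see [HRFParams-class].
#' @return an [HRFParams-class] object.
#' @export
hrfParams <- function(peakDelay = 6, undershootDelay = 16,
                      peakDispersion = 1, undershootDispersion = 1,
                      undershootRatio = 1 / 6) {
  methods::new("HRFParams", peakDelay = peakDelay,
               undershootDelay = undershootDelay,
               peakDispersion = peakDispersion,
               undershootDispersion = undershootDispersion,
               undershootRatio = undershootRatio)
}

#' SyntheticConfig: full generative specification of a synthetic dataset
#'
#' Signal model per trial, channel c and epoch time tau:
#' \deqn{x(\tau, c) = \beta\, h(\tau)\, g_c\, [\mathrm{yes}] +
#'   \sigma_{sh} z(\tau) + \sigma_{ch}\varepsilon_c(\tau) + d_c(\tau)}
#' with a shared white latent process z, independent channel noise, and an
#' optional per-channel AR(1) drift (coefficient phi, innovation sd
#' sigma_drift), all drawn fresh per trial. The effect enters "yes" trials
#' only.
#'
#' @slot nDays,sessionsPerDay,nChannels positive integers.
#' @slot trialsYes,trialsNo per-session trial counts per condition.
#' @slot epochWindow `(start, end)` seconds relative to onset; start < 0 < end
#'   so a baseline window exists. Samples cover `[start, end)`.
#' @slot samplingRate Hz.
#' @slot effectAmplitude beta >= 0, applied to "yes" trials.
#' @slot channelLoadings per-channel effect gains g_c (length 1 or nChannels).
#' @slot sharedNoiseSd,channelNoiseSd sigma_shared, sigma_chan (>= 0).
#' @slot driftAr,driftInnovationSd AR(1) drift phi in `[0,1)` and innovation sd.
#' @slot hrfParams an [HRFParams-class].
#' @slot seed integer; generation is bit-reproducible given the full config.
#' @seealso [syntheticConfig()], [generateDataset()], [syntheticPreset()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nDays = "integer", sessionsPerDay = "integer",
                 trialsYes = "integer", trialsNo = "integer",
                 nChannels = "integer", epochWindow = "numeric",
                 samplingRate = "numeric", effectAmplitude = "numeric",
                 channelLoadings = "numeric",
                 sharedNoiseSd = "numeric", channelNoiseSd = "numeric",
                 driftAr = "numeric", driftInnovationSd = "numeric",
                 hrfParams = "HRFParams", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  v <- character()
  if (object@nDays < 1L) v <- c(v, "nDays must be >= 1")
  if (object@sessionsPerDay < 1L) v <- c(v, "sessionsPerDay must be >= 1")
  if (object@trialsYes < 0L || object@trialsNo < 0L)
    v <- c(v, "trial counts must be >= 0")
  if (object@nChannels < 1L) v <- c(v, "nChannels must be >= 1")
  if (length(object@epochWindow) != 2L ||
      !(object@epochWindow[1] < 0 && 0 < object@epochWindow[2]))
    v <- c(v, "epochWindow must satisfy start < 0 < end (a pre-stimulus baseline must exist)")
  if (object@samplingRate <= 0) v <- c(v, "samplingRate must be > 0")
  if (object@effectAmplitude < 0) v <- c(v, "effectAmplitude must be >= 0")
  if (!length(object@channelLoadings) %in% c(1L, object@nChannels))
    v <- c(v, "channelLoadings must have length 1 or nChannels")
  if (object@sharedNoiseSd < 0 || object@channelNoiseSd < 0 ||
      object@driftInnovationSd < 0)
    v <- c(v, "noise sds must be >= 0")
  if (object@driftAr < 0 || object@driftAr >= 1)
    v <- c(v, "driftAr must lie in [0, 1)")
  if (length(v)) v else TRUE
})

#' Construct a SyntheticConfig
#'
#' @param nDays,sessionsPerDay dataset structure (days, sessions per day).
#' @param trialsPerCondition default per-session trial count for both
#'   conditions; override `trialsYes`/`trialsNo` to create imbalance.
#' @param trialsYes,trialsNo per-session trial counts per condition.
#' @param nChannels number of channels (default 20).
#' @param epochWindow epoch `(start, end)` in seconds, default `c(-5, 20)`.
#' @param samplingRate Hz, default 2.
#' @param effectAmplitude condition-locked response amplitude beta (>= 0).
#' @param channelLoadings per-channel effect gains (default 1 for all).
#' @param sharedNoiseSd,channelNoiseSd noise sds; the implied inter-channel
#'   correlation is given by [channelCorrelation()].
#' @param driftAr,driftInnovationSd AR(1) drift coefficient and innovation sd.
#' @param hrf an [HRFParams-class] object.
#' @param seed integer seed.
#' @return a validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(sessionsPerDay = 2, trialsPerCondition = 3,
#'                        nChannels = 4, effectAmplitude = 1, seed = 7)
#' channelCorrelation(cfg)
#' @export
syntheticConfig <- function(nDays = 1L, sessionsPerDay = 10L,
                            trialsPerCondition = 10L,
                            trialsYes = trialsPerCondition,
                            trialsNo = trialsPerCondition,
                            nChannels = 20L, epochWindow = c(-5, 20),
                            samplingRate = 2, effectAmplitude = 0,
                            channelLoadings = 1,
                            sharedNoiseSd = 1, channelNoiseSd = 1,
                            driftAr = 0, driftInnovationSd = 0,
                            hrf = hrfParams(), seed = 1L) {
  methods::new("SyntheticConfig",
               nDays = as.integer(nDays),
               sessionsPerDay = as.integer(sessionsPerDay),
               trialsYes = as.integer(trialsYes),
               trialsNo = as.integer(trialsNo),
               nChannels = as.integer(nChannels),
               epochWindow = as.numeric(epochWindow),
               samplingRate = as.numeric(samplingRate),
               effectAmplitude = as.numeric(effectAmplitude),
               channelLoadings = as.numeric(channelLoadings),
               sharedNoiseSd = as.numeric(sharedNoiseSd),
               channelNoiseSd = as.numeric(channelNoiseSd),
               driftAr = as.numeric(driftAr),
               driftInnovationSd = as.numeric(driftInnovationSd),
               hrfParams = hrf, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Chance-level result
# ---------------------------------------------------------------------------

#' ChanceTestResult: exact binomial assessment of a classification accuracy
#'
#' @slot k correct count; @slot n trial count; @slot chance chance level.
#' @slot pValue exact binomial tail probability (no normal approximation).
#' @slot alternative `"greater"` (default) or `"two.sided"`.
#' @slot ci two-sided Clopper-Pearson interval for the accuracy at level
#'   `1 - alpha`.
#' @slot alpha significance level; @slot significant `pValue < alpha`.
#' @seealso [accuracyBinomialTest()]
#' @exportClass ChanceTestResult
setClass("ChanceTestResult",
  representation(k = "integer", n = "integer", chance = "numeric",
                 pValue = "numeric", alternative = "character",
                 ci = "numeric", alpha = "numeric", significant = "logical"))
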