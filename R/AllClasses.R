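#' @import methods
#' @importFrom BiocGenerics cbind
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# Default 14-channel consumer-headset montage (10-20 positions).
EMOTIV_MONTAGE <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

# Condition labels: communication delay x information dropout, Low/High each.
WORKLOAD_CONDITIONS <- c("LowLow", "LowHigh", "HighLow", "HighHigh")

#' EEGRecording: one subject-trial of multi-channel EEG
#'
#' A channel-by-sample matrix in microvolts together with its montage labels,
#' sampling rate, condition label (`NA` for a resting baseline recording) and
#' a per-sample artifact mask (`TRUE` = rejected).  Ground truth for injected
#' synthetic artifacts, when present, lives in `@artifactTruth` so tests can
#' assert against known blink/spike locations.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of montage names, one per row.
#' @slot condition condition label or `NA_character_` for baseline.
#' @slot repetition repetition index within condition (`NA` for baseline).
#' @slot subjectId subject identifier.
#' @slot artifactMask logical vector, one entry per sample.
#' @slot artifactTruth list recording injected artifact ground truth.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    condition = "character",
    repetition = "integer",
    subjectId = "character",
    artifactMask = "logical",
    artifactTruth = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data) || !all(is.finite(object@data)))
    msg <- c(msg, "data must be a finite numeric matrix")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "channelLabels length must equal the channel count")
  if (length(object@artifactMask) != ncol(object@data))
    msg <- c(msg, "artifactMask length must equal the sample count")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelLabels montage labels, one per channel.
#' @param condition condition label (`NA` for baseline recordings).
#' @param repetition repetition index within the condition.
#' @param subjectId subject identifier.
#' @param artifactMask optional logical mask (defaults to all-`FALSE`).
#' @param artifactTruth optional list of injected-artifact ground truth.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fs, channelLabels = rownames(data),
                         condition = NA_character_, repetition = NA_integer_,
                         subjectId = "S1", artifactMask = NULL,
                         artifactTruth = list()) {
  data <- as.matrix(data)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channelLabels
  if (is.null(artifactMask)) artifactMask <- rep(FALSE, ncol(data))
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels),
      condition = as.character(condition),
      repetition = as.integer(repetition),
      subjectId = as.character(subjectId),
      artifactMask = as.logical(artifactMask),
      artifactTruth = artifactTruth)
}

#' SubjectDataset: everything recorded for one synthetic subject
#'
#' @slot subjectId subject identifier.
#' @slot trials list of [EEGRecording-class], one per condition x repetition.
#' @slot baseline resting [EEGRecording-class] with no condition label.
#' @slot hrSeries list of numeric heart-rate series (bpm, 8 Hz), one per trial.
#' @slot atwitScores integer subjective workload responses (1-7), one per trial.
#' @slot trialInfo data.frame with columns condition, repetition.
#' @exportClass SubjectDataset
setClass("SubjectDataset",
  representation(
    subjectId = "character",
    trials = "list",
    baseline = "EEGRecording",
    hrSeries = "list",
    atwitScores = "integer",
    trialInfo = "data.frame"
  )
)

setValidity("SubjectDataset", function(object) {
  msg <- character()
  nt <- length(object@trials)
  if (length(object@hrSeries) != nt || length(object@atwitScores) != nt ||
      nrow(object@trialInfo) != nt)
    msg <- c(msg, "trials, hrSeries, atwitScores and trialInfo must align")
  if (any(object@atwitScores < 1L | object@atwitScores > 7L))
    msg <- c(msg, "atwitScores must lie in [1, 7]")
  if (any(unlist(object@hrSeries) <= 0))
    msg <- c(msg, "heart-rate values must be positive")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: parameters of the synthetic workload experiment
#'
#' Defaults mirror the study design this package emulates: 16 subjects,
#' 14-channel 128 Hz montage, four conditions (delay x dropout, Low/High)
#' each repeated twice in 4-minute trials, plus a 1-minute resting baseline.
#' The effect map lists the (channel, band) pairs whose oscillatory power
#' scales with workload level; heart-rate and subjective-workload parameters
#' are per-condition means/standard deviations.
#'
#' @slot nSubjects number of subjects.
#' @slot channelLabels montage names.
#' @slot fs sampling rate (Hz).
#' @slot trialSeconds trial duration (s).
#' @slot baselineSeconds baseline recording duration (s).
#' @slot repetitions repetitions per condition.
#' @slot conditions ordered condition labels.
#' @slot workloadLevels numeric ordinal workload level per condition.
#' @slot carrierBands data.frame (name, low, high) of synthesized bands.
#' @slot effectMap data.frame (channel, band, slope): multiplicative power
#'   slope per workload level.
#' @slot backgroundSd pink-background amplitude (microvolt sd).
#' @slot carrierSd per-band oscillation amplitude (microvolt sd).
#' @slot subjectGainSd log-sd of per-(subject, channel) amplitude gain.
#' @slot trialGainSd log-sd of per-trial broadband power gain.
#' @slot slopeJitterSd log-sd of per-subject effect-slope responsiveness.
#' @slot hrParams data.frame (condition, mean, sd) of heart rate, bpm.
#' @slot hrTraitSd between-subject resting heart-rate offset sd (bpm).
#' @slot hrResponseScale per-trial condition-response sd as a fraction of the
#'   condition's reported std.
#' @slot hrResponseCap upper bound on the per-trial response sd (bpm).
#' @slot hrFs heart-rate sampling rate (Hz).
#' @slot atwitParams data.frame (condition, mean, sd) on the 1-7 scale.
#' @slot atwitTraitSd between-subject response-style sd.
#' @slot seed integer cohort seed.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nSubjects = "integer",
    channelLabels = "character",
    fs = "numeric",
    trialSeconds = "numeric",
    baselineSeconds = "numeric",
    repetitions = "integer",
    conditions = "character",
    workloadLevels = "numeric",
    carrierBands = "data.frame",
    effectMap = "data.frame",
    backgroundSd = "numeric",
    carrierSd = "numeric",
    subjectGainSd = "numeric",
    trialGainSd = "numeric",
    slopeJitterSd = "numeric",
    hrParams = "data.frame",
    hrTraitSd = "numeric",
    hrResponseScale = "numeric",
    hrResponseCap = "numeric",
    hrFs = "numeric",
    atwitParams = "data.frame",
    atwitTraitSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@conditions) != 4L)
    msg <- c(msg, "conditions must have exactly 4 entries")
  if (length(object@workloadLevels) != length(object@conditions))
    msg <- c(msg, "workloadLevels must align with conditions")
  if (object@fs <= 2 * max(object@carrierBands$high))
    msg <- c(msg, "fs must exceed twice the highest synthesized band edge")
  if (any(object@hrParams$sd < 0) || any(object@atwitParams$sd < 0))
    msg <- c(msg, "all standard deviations must be >= 0")
  if (nrow(object@effectMap) &&
      !all(object@effectMap$channel %in% object@channelLabels))
    msg <- c(msg, "effectMap channels must be in channelLabels")
  if (nrow(object@effectMap) &&
      !all(object@effectMap$band %in% object@carrierBands$name))
    msg <- c(msg, "effectMap bands must be in carrierBands")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: windows-by-features matrix of spectral workload features
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"values"` with features as rows (baseline-relative band powers
#' and, optionally, ratio indices) and analysis windows as columns.
#' `rowData` carries `channel`, `band` and `type` (`"power"` or `"ratio"`);
#' `colData` carries `condition`, `repetition`, `window_start_s`, `subject`.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  v <- SummarizedExperiment::assay(object, "values")
  if (!all(is.finite(v)))
    msg <- c(msg, "feature values must be finite")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("channel", "band", "type") %in% colnames(rd)))
    msg <- c(msg, "rowData must have channel, band, type")
  pow <- rd$type == "power"
  if (any(pow) && any(v[pow, , drop = FALSE] <= 0))
    msg <- c(msg, "power features must be strictly positive")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must have a condition column")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values features x windows numeric matrix.
#' @param channel,band,type per-feature metadata vectors.
#' @param condition per-window condition labels.
#' @param windowStart per-window start times (s).
#' @param subjectId subject identifier.
#' @param repetition per-window repetition index.
#' @return A [FeatureTable-class].
#' @export
FeatureTable <- function(values, channel, band, type, condition,
                         windowStart = rep(NA_real_, ncol(values)),
                         subjectId = "S1",
                         repetition = rep(NA_integer_, ncol(values))) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(channel = channel, band = band,
                                   type = type, row.names = rownames(values)),
    colData = S4Vectors::DataFrame(condition = condition,
                                   repetition = repetition,
                                   window_start_s = windowStart,
                                   subject = rep(subjectId, ncol(values)))
  )
  new("FeatureTable", se)
}

#' FeatureRanking: one subject's ordered feature list
#'
#' @slot subjectId subject identifier.
#' @slot method ranking criterion: `"JMI"`, `"InfoGain"` or `"TStat"`.
#' @slot orderedFeatures feature ids, best first (a permutation of the input
#'   feature universe).
#' @slot scores selection-criterion value at each position (per-step greedy
#'   gains for JMI, stored as-is).
#' @exportClass FeatureRanking
setClass("FeatureRanking",
  representation(subjectId = "character", method = "character",
                 orderedFeatures = "character", scores = "numeric")
)

setValidity("FeatureRanking", function(object) {
  msg <- character()
  if (length(object@orderedFeatures) != length(object@scores))
    msg <- c(msg, "orderedFeatures and scores must align")
  if (anyDuplicated(object@orderedFeatures))
    msg <- c(msg, "orderedFeatures must not contain duplicates")
  if (!object@method %in% c("JMI", "InfoGain", "TStat"))
    msg <- c(msg, "method must be JMI, InfoGain or TStat")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureRanking
#' @param subjectId subject identifier.
#' @param method ranking criterion label.
#' @param orderedFeatures feature ids best-first.
#' @param scores criterion values aligned to `orderedFeatures`.
#' @export
FeatureRanking <- function(subjectId, method, orderedFeatures,
                           scores = rep(NA_real_, length(orderedFeatures))) {
  new("FeatureRanking", subjectId = as.character(subjectId),
      method = method, orderedFeatures = as.character(orderedFeatures),
      scores = as.numeric(scores))
}

#' ConsensusResult: population-level consensus feature scores
#'
#' @slot scores named numeric, total rank-position-weighted score per feature
#'   that appeared in at least one subject's top-k list, descending.
#' @slot appearanceCounts named integer appearance counts, aligned to scores.
#' @slot orderedFeatures scored feature ids by descending score (ties broken
#'   by higher appearance count, then feature id).
#' @slot pooledListSize n_subjects x top_k.
#' @slot topK pooling depth.
#' @slot nSubjects number of contributing rankings.
#' @slot featureUniverse the full feature set the rankings covered.
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(scores = "numeric", appearanceCounts = "integer",
                 orderedFeatures = "character", pooledListSize = "integer",
                 topK = "integer", nSubjects = "integer",
                 featureUniverse = "character")
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (object@pooledListSize != object@nSubjects * object@topK)
    msg <- c(msg, "pooledListSize must equal nSubjects * topK")
  if (any(object@appearanceCounts < 1L))
    msg <- c(msg, "every scored feature must appear at least once")
  if (any(object@scores <= 0) || any(object@scores > object@nSubjects))
    msg <- c(msg, "scores must lie in (0, nSubjects]")
  if (length(msg)) msg else TRUE
})

#' EvalProtocol: classifier evaluation parameters
#'
#' @slot trainFraction fraction of windows used for training (default 0.7).
#' @slot cvFolds folds for the training-set cross-validation sanity check.
#' @slot nRepeats number of seeded stratified splits.
#' @slot seed base seed for the splits.
#' @slot alpha significance level of the stopping t-tests.
#' @slot consecutiveRequired consecutive non-significant steps that stop the
#'   feature-count search.
#' @exportClass EvalProtocol
setClass("EvalProtocol",
  representation(trainFraction = "numeric", cvFolds = "integer",
                 nRepeats = "integer", seed = "integer", alpha = "numeric",
                 consecutiveRequired = "integer")
)

setValidity("EvalProtocol", function(object) {
  msg <- character()
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (object@cvFolds < 2L)
    msg <- c(msg, "cvFolds must be >= 2")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct an EvalProtocol
#' @param trainFraction training fraction of each stratified split.
#' @param cvFolds cross-validation folds on the training portion.
#' @param nRepeats number of repeated seeded splits.
#' @param seed base seed.
#' @param alpha stopping-test significance level.
#' @param consecutiveRequired consecutive non-significant steps required.
#' @export
evalProtocol <- function(trainFraction = 0.7, cvFolds = 10, nRepeats = 30,
                         seed = 1L, alpha = 0.05, consecutiveRequired = 3) {
  new("EvalProtocol", trainFraction = trainFraction,
      cvFolds = as.integer(cvFolds), nRepeats = as.integer(nRepeats),
      seed = as.integer(seed), alpha = alpha,
      consecutiveRequired = as.integer(consecutiveRequired))
}

#' AccuracyCurve: accuracy as a function of ranked-feature count
#'
#' @slot featureCounts increasing feature counts.
#' @slot meanAcc mean held-out accuracy (%) per count.
#' @slot sdAcc standard deviation (%) per count.
#' @slot perRepeat list of per-repeat held-out scores (%), one vector per count.
#' @slot cvMeanAcc mean training-portion cross-validation accuracy (%) per
#'   count (`NA` when not computed).
#' @exportClass AccuracyCurve
setClass("AccuracyCurve",
  representation(featureCounts = "integer", meanAcc = "numeric",
                 sdAcc = "numeric", perRepeat = "list", cvMeanAcc = "numeric")
)

setValidity("AccuracyCurve", function(object) {
  msg <- character()
  n <- length(object@featureCounts)
  if (length(object@meanAcc) != n || length(object@sdAcc) != n ||
      length(object@perRepeat) != n)
    msg <- c(msg, "curve slots must have equal length")
  if (any(object@meanAcc < 0 | object@meanAcc > 100))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' RepeatedMeasures: one scalar per subject per condition
#'
#' @slot values subjects x conditions numeric matrix, no missing cells.
#' @slot metricName metric label (`"ATWIT"`, `"HR"`, `"EEG"`, ...).
#' @slot conditionLabels the condition labels (column names).
#' @exportClass RepeatedMeasures
setClass("RepeatedMeasures",
  representation(values = "matrix", metricName = "character",
                 conditionLabels = "character")
)

setValidity("RepeatedMeasures", function(object) {
  msg <- character()
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must have no missing cells")
  if (nrow(object@values) < 2L)
    msg <- c(msg, "at least 2 subjects are required")
  if (ncol(object@values) != length(object@conditionLabels))
    msg <- c(msg, "conditionLabels must match the column count")
  if (length(msg)) msg else TRUE
})

#' Construct a RepeatedMeasures matrix
#' @param values subjects x conditions matrix.
#' @param metricName metric label.
#' @param conditionLabels condition labels (defaults to column names).
#' @export
repeatedMeasures <- function(values, metricName = "metric",
                             conditionLabels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(conditionLabels))
    conditionLabels <- paste0("C", seq_len(ncol(values)))
  colnames(values) <- conditionLabels
  new("RepeatedMeasures", values = values, metricName = metricName,
      conditionLabels = conditionLabels)
}

#' ValidationReport: normality gate, omnibus and post-hoc results
#'
#' @slot metricName metric label.
#' @slot normalityP Shapiro-Wilk p on the raw residuals.
#' @slot normalityPLog Shapiro-Wilk p after log transform (`NA` if not run).
#' @slot transformed whether the log transform was applied.
#' @slot useNonparametric whether the nonparametric route was taken.
#' @slot friedmanChi2 Friedman chi-squared statistic.
#' @slot friedmanP asymptotic Friedman p-value.
#' @slot posthoc data.frame: pair, p, significant — 6 pairwise Wilcoxon tests.
#' @slot bonferroniAlpha family alpha divided by the number of pairs.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(metricName = "character", normalityP = "numeric",
                 normalityPLog = "numeric", transformed = "logical",
                 useNonparametric = "logical", friedmanChi2 = "numeric",
                 friedmanP = "numeric", posthoc = "data.frame",
                 bonferroniAlpha = "numeric")
)

setValidity("ValidationReport", function(object) {
  msg <- character()
  k <- length(object@bonferroniAlpha)
  if (nrow(object@posthoc) != 6L)
    msg <- c(msg, "posthoc must contain exactly choose(4, 2) = 6 pairs")
  if (length(msg)) msg else TRUE
})
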