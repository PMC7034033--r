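#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `eegData()`, `samplingRate()`, `channelLabels()`, `conditionLabel()`,
#' `subjectId()`, `artifactMask()`, `trials()`, `baselineRecording()`,
#' `heartRate()`, `atwitScores()`, `featureIds()`, `conditionLabels()`,
#' `rankedFeatures()`, `rankingScores()`, `rankingMethod()`,
#' `consensusScoresOf()`, `appearanceCounts()`, `featureCounts()`,
#' `meanAccuracy()`, `sdAccuracy()`, `perRepeatScores()`, `measuresMatrix()`.
#'
#' @param x an object of the corresponding class.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))
#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("baselineRecording",
           function(x) standardGeneric("baselineRecording"))
#' @rdname accessors
#' @export
setGeneric("heartRate", function(x) standardGeneric("heartRate"))
#' @rdname accessors
#' @export
setGeneric("atwitScores", function(x) standardGeneric("atwitScores"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setGeneric("rankedFeatures", function(x) standardGeneric("rankedFeatures"))
#' @rdname accessors
#' @export
setGeneric("rankingScores", function(x) standardGeneric("rankingScores"))
#' @rdname accessors
#' @export
setGeneric("rankingMethod", function(x) standardGeneric("rankingMethod"))
#' @rdname accessors
#' @export
setGeneric("consensusScoresOf",
           function(x) standardGeneric("consensusScoresOf"))
#' @rdname accessors
#' @export
setGeneric("appearanceCounts", function(x) standardGeneric("appearanceCounts"))
#' @rdname accessors
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))
#' @rdname accessors
#' @export
setGeneric("perRepeatScores", function(x) standardGeneric("perRepeatScores"))
#' @rdname accessors
#' @export
setGeneric("measuresMatrix", function(x) standardGeneric("measuresMatrix"))

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("conditionLabel", "EEGRecording", function(x) x@condition)
#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("artifactMask", "EEGRecording", function(x) x@artifactMask)

#' @rdname accessors
setMethod("subjectId", "SubjectDataset", function(x) x@subjectId)
#' @rdname accessors
setMethod("trials", "SubjectDataset", function(x) x@trials)
#' @rdname accessors
setMethod("baselineRecording", "SubjectDataset", function(x) x@baseline)
#' @rdname accessors
setMethod("heartRate", "SubjectDataset", function(x) x@hrSeries)
#' @rdname accessors
setMethod("atwitScores", "SubjectDataset", function(x) x@atwitScores)

#' @rdname accessors
setMethod("featureIds", "FeatureTable", function(x) rownames(x))
#' @rdname accessors
setMethod("conditionLabels", "FeatureTable",
          function(x) SummarizedExperiment::colData(x)$condition)
#' @rdname accessors
setMethod("subjectId", "FeatureTable",
          function(x) unique(SummarizedExperiment::colData(x)$subject))

#' @rdname accessors
setMethod("subjectId", "FeatureRanking", function(x) x@subjectId)
#' @rdname accessors
setMethod("rankedFeatures", "FeatureRanking", function(x) x@orderedFeatures)
#' @rdname accessors
setMethod("rankingScores", "FeatureRanking", function(x) x@scores)
#' @rdname accessors
setMethod("rankingMethod", "FeatureRanking", function(x) x@method)

#' @rdname accessors
setMethod("consensusScoresOf", "ConsensusResult", function(x) x@scores)
#' @rdname accessors
setMethod("appearanceCounts", "ConsensusResult", function(x) x@appearanceCounts)
#' @rdname accessors
setMethod("rankedFeatures", "ConsensusResult", function(x) x@orderedFeatures)

#' @rdname accessors
setMethod("featureCounts", "AccuracyCurve", function(x) x@featureCounts)
#' @rdname accessors
setMethod("meanAccuracy", "AccuracyCurve", function(x) x@meanAcc)
#' @rdname accessors
setMethod("sdAccuracy", "AccuracyCurve", function(x) x@sdAcc)
#' @rdname accessors
setMethod("perRepeatScores", "AccuracyCurve", function(x) x@perRepeat)

#' @rdname accessors
setMethod("measuresMatrix", "RepeatedMeasures", function(x) x@values)
#' @rdname accessors
setMethod("conditionLabels", "RepeatedMeasures", function(x) x@conditionLabels)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", object@subjectId,
      if (is.na(object@condition)) "(baseline)" else object@condition, "\n")
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat(sprintf("  masked samples: %d\n", sum(object@artifactMask)))
})

setMethod("show", "SubjectDataset", function(object) {
  cat("SubjectDataset:", object@subjectId, "-", length(object@trials),
      "trials +", "baseline\n")
  print(table(object@trialInfo$condition))
})

setMethod("show", "FeatureRanking", function(object) {
  cat(sprintf("FeatureRanking (%s) for %s: %d features\n", object@method,
              object@subjectId, length(object@orderedFeatures)))
  n <- min(5L, length(object@orderedFeatures))
  cat("  top:", paste(object@orderedFeatures[seq_len(n)], collapse = ", "),
      "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d subjects, top-%d pooling (%d pooled)\n",
              object@nSubjects, object@topK, object@pooledListSize))
  n <- min(5L, length(object@orderedFeatures))
  head <- object@orderedFeatures[seq_len(n)]
  cat("  leading features:",
      paste(sprintf("%s (%.1f)", head, object@scores[head]), collapse = ", "),
      "\n")
})

setMethod("show", "AccuracyCurve", function(object) {
  cat(sprintf("AccuracyCurve: %d counts, accuracy %.1f%% to %.1f%%\n",
              length(object@featureCounts), min(object@meanAcc),
              max(object@meanAcc)))
})

setMethod("show", "RepeatedMeasures", function(object) {
  cat(sprintf("RepeatedMeasures (%s): %d subjects x %d conditions\n",
              object@metricName, nrow(object@values), ncol(object@values)))
  print(round(colMeans(object@values), 2))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport (%s)\n", object@metricName))
  cat(sprintf("  Shapiro-Wilk p = %.4g%s\n", object@normalityP,
              if (object@transformed)
                sprintf(" (log-transformed: p = %.4g)", object@normalityPLog)
              else ""))
  cat(sprintf("  Friedman chi2 = %.3f, p = %.4g\n", object@friedmanChi2,
              object@friedmanP))
  cat(sprintf("  Wilcoxon post-hoc at p < %.4f:\n", object@bonferroniAlpha))
  ph <- object@posthoc
  for (i in seq_len(nrow(ph)))
    cat(sprintf("    %-20s p = %.4f %s\n", ph$pair[i], ph$p[i],
                if (ph$significant[i]) "*" else ""))
})
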