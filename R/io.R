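#' @include AllClasses.R
NULL

#' Write / read a recording as long-format CSV
#'
#' Columns: subject, condition, repetition, channel, sample_index, value_uV.
#' The sampling rate is stored in a `# fs=` comment on the first line.
#'
#' @param rec an [EEGRecording-class].
#' @param path output CSV path.
#' @return `writeRecordingCsv`: the path, invisibly.  `readRecordingCsv`:
#'   an [EEGRecording-class].
#' @export
writeRecordingCsv <- function(rec, path) {
  long <- data.frame(
    subject = rec@subjectId,
    condition = rec@condition,
    repetition = rec@repetition,
    channel = rep(rec@channelLabels, each = ncol(rec@data)),
    sample_index = rep(seq_len(ncol(rec@data)), nrow(rec@data)),
    value_uV = as.numeric(t(rec@data)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec@fs), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordingCsv
#' @export
readRecordingCsv <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub("# fs=", "", header, fixed = TRUE))
  long <- utils::read.csv(path, comment.char = "#")
  chs <- unique(long$channel)
  n <- max(long$sample_index)
  dat <- matrix(NA_real_, length(chs), n, dimnames = list(chs, NULL))
  for (ch in chs)
    dat[ch, long$sample_index[long$channel == ch]] <-
      long$value_uV[long$channel == ch]
  EEGRecording(dat, fs, chs,
               condition = as.character(long$condition[1]),
               repetition = as.integer(long$repetition[1]),
               subjectId = as.character(long$subject[1]))
}

#' Persist a feature table as CSV
#'
#' One row per window; feature columns use the `<Band><Channel>` ids plus
#' subject, condition, repetition and window_start_s metadata columns.
#'
#' @param table a [FeatureTable-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  cd <- SummarizedExperiment::colData(table)
  out <- cbind(
    data.frame(subject = cd$subject, condition = cd$condition,
               repetition = cd$repetition,
               window_start_s = cd$window_start_s),
    as.data.frame(t(SummarizedExperiment::assay(table, "values"))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Persist per-subject rankings as CSV
#'
#' Columns: subject, method, rank_position, feature_id, score.
#'
#' @param rankings list of [FeatureRanking-class] objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeRankings <- function(rankings, path) {
  rows <- lapply(rankings, function(r)
    data.frame(subject = r@subjectId, method = r@method,
               rank_position = seq_along(r@orderedFeatures),
               feature_id = r@orderedFeatures, score = r@scores))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankings
#' @export
readRankings <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$subject), function(d) {
    d <- d[order(d$rank_position), ]
    FeatureRanking(d$subject[1], d$method[1], d$feature_id, d$score)
  })
}

#' Persist a consensus result as CSV
#'
#' @param result a [ConsensusResult-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeConsensus <- function(result, path) {
  utils::write.csv(consensusTable(result), path, row.names = FALSE)
  invisible(path)
}

#' Persist a validation report as JSON
#'
#' @param report a [ValidationReport-class].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  obj <- list(metric = report@metricName,
              normality_p = report@normalityP,
              normality_p_log = report@normalityPLog,
              transformed = report@transformed,
              use_nonparametric = report@useNonparametric,
              friedman_chi2 = report@friedmanChi2,
              friedman_p = report@friedmanP,
              bonferroni_alpha = report@bonferroniAlpha,
              posthoc = report@posthoc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Persist an accuracy curve as CSV
#'
#' Main file: feature_count, mean_acc_pct, std_acc_pct, cv_mean_acc_pct.
#' A companion `*_repeats.csv` keeps the raw per-repeat scores for the
#' stopping-test audit trail.
#'
#' @param curve an [AccuracyCurve-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeAccuracyCurve <- function(curve, path) {
  utils::write.csv(data.frame(feature_count = curve@featureCounts,
                              mean_acc_pct = curve@meanAcc,
                              std_acc_pct = curve@sdAcc,
                              cv_mean_acc_pct = curve@cvMeanAcc),
                   path, row.names = FALSE)
  rep <- do.call(rbind, lapply(seq_along(curve@featureCounts), function(i)
    data.frame(feature_count = curve@featureCounts[i],
               repeat_index = seq_along(curve@perRepeat[[i]]),
               acc_pct = curve@perRepeat[[i]])))
  utils::write.csv(rep, sub("\\.csv$", "_repeats.csv", path),
                   row.names = FALSE)
  invisible(path)
}
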