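#' @include AllClasses.R
NULL

.rankTable <- function(table, method, nBins) {
  switch(method,
         jmi = jmiRank(table, nBins),
         infogain = infoGainRank(table, nBins),
         ttest = tTestRank(table),
         stop("unknown ranking method: ", method))
}

#' Run the full workload-indicator discovery pipeline
#'
#' Simulate (or accept) a cohort, preprocess every recording, extract
#' baseline-relative band-power features (plus ratio indices for the
#' reference table and correlation screen), rank features per subject,
#' pool the rankings into the consensus weighting, evaluate the consensus
#' ordering with per-subject LDA accuracy curves grand-averaged across the
#' cohort, fix the feature-set size with the stopping criterion, and run
#' the three-metric validation battery (subjective workload, heart rate,
#' consensus EEG metric).
#'
#' @param config a [CohortConfig-class] describing the cohort.
#' @param protocol an [EvalProtocol-class] for the classifier evaluation.
#' @param bands band set for the classified features.
#' @param ranker `"jmi"`, `"infogain"` or `"ttest"`.
#' @param nBins discretization bins for the information-based rankers.
#' @param topK consensus pooling depth.
#' @param maxCurveFeatures largest evaluated prefix of the consensus
#'   ordering (default: all features).
#' @param cohort optionally, a pre-generated cohort (list of
#'   [SubjectDataset-class]); `config` is then only used for band/condition
#'   settings.
#' @param outDir if non-`NULL`, all stage outputs and a reproducibility
#'   manifest are written there.
#' @param familyAlpha family-wise alpha of the validation battery.
#' @return List with elements `featureTables`, `referenceTable`, `screen`,
#'   `rankings`, `consensus`, `curve`, `selectedCount`, `topSet`, `reports`
#'   (ATWIT/HR/EEG [ValidationReport-class]), and `manifest`.
#' @export
runWorkloadPipeline <- function(config = cohortConfig(),
                                protocol = evalProtocol(),
                                bands = bandsClassify3(),
                                ranker = c("jmi", "infogain", "ttest"),
                                nBins = 5, topK = 10,
                                maxCurveFeatures = NULL, cohort = NULL,
                                outDir = NULL, familyAlpha = 0.05) {
  ranker <- match.arg(ranker)
  warnings <- character(0)
  if (is.null(cohort)) cohort <- generateCohort(config)

  withRatios <- lapply(cohort, subjectFeatureTable, bands = bands,
                       includeRatios = TRUE, preprocess = TRUE)
  screen <- correlationScreen(withRatios[[1]])
  tables <- lapply(withRatios, bandOnly)

  rankings <- lapply(tables, .rankTable, method = ranker, nBins = nBins)
  consensus <- consensusScores(rankings, topK)

  ordered <- rankedFeatures(consensus)
  if (is.null(maxCurveFeatures)) maxCurveFeatures <- length(ordered)
  maxCurveFeatures <- min(maxCurveFeatures, length(ordered))
  curves <- lapply(tables, accuracyCurve, ranking = ordered,
                   protocol = protocol, maxFeatures = maxCurveFeatures)
  curve <- grandAverageCurve(curves)
  selectedCount <- withCallingHandlers(
    stoppingCriterion(curve, protocol),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  topSet <- selectTopSet(consensus, as.integer(selectedCount))

  reports <- list(
    ATWIT = validateMetric(atwitMeasures(cohort, config@conditions),
                           familyAlpha),
    HR = validateMetric(hrMeasures(cohort, config@conditions), familyAlpha),
    EEG = validateMetric(aggregateEegMetric(tables, topSet,
                                            config@conditions), familyAlpha))

  result <- list(featureTables = tables, referenceTable = withRatios,
                 screen = screen, rankings = rankings,
                 consensus = consensus, curve = curve,
                 selectedCount = as.integer(selectedCount),
                 topSet = topSet, reports = reports)
  result$manifest <- .writeOutputs(result, cohort, config, protocol, ranker,
                                   topK, outDir, warnings)
  result
}

.writeOutputs <- function(result, cohort, config, protocol, ranker, topK,
                          outDir, warnings) {
  manifest <- list(
    seed = config@seed,
    subject_seeds = attr(cohort, "manifest"),
    ranker = ranker, top_k = topK,
    n_subjects = length(cohort),
    selected_count = result$selectedCount,
    top_set = result$topSet,
    protocol = list(train_fraction = protocol@trainFraction,
                    cv_folds = protocol@cvFolds,
                    n_repeats = protocol@nRepeats,
                    seed = protocol@seed, alpha = protocol@alpha,
                    consecutive_required = protocol@consecutiveRequired),
    r_version = as.character(getRversion()),
    warnings = warnings)
  if (is.null(outDir)) return(manifest)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(result$featureTables)) {
    p <- file.path(outDir, sprintf("features_%s.csv",
                                   subjectId(result$featureTables[[i]])[1]))
    writeFeatureTable(result$featureTables[[i]], p)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "rankings.csv")
  writeRankings(result$rankings, p); paths <- c(paths, p)
  p <- file.path(outDir, "consensus.csv")
  writeConsensus(result$consensus, p); paths <- c(paths, p)
  p <- file.path(outDir, "top_set.txt")
  writeLines(result$topSet, p); paths <- c(paths, p)
  p <- file.path(outDir, "accuracy_curve.csv")
  writeAccuracyCurve(result$curve, p); paths <- c(paths, p)
  for (nm in names(result$reports)) {
    p <- file.path(outDir, sprintf("validation_%s.json", tolower(nm)))
    writeValidationReport(result$reports[[nm]], p)
    paths <- c(paths, p)
  }
  manifest$checksums <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest
}

#' Compare the three feature-ranking methods
#'
#' For each ranking criterion (JMI, information gain, t statistic) the
#' per-subject rankings are evaluated two ways: following each subject's own
#' ranking (`FS`) and following the cohort consensus ordering
#' (`FS + weights`).  The stopping criterion fixes a feature count for each
#' of the six curves, tabulated side by side.
#'
#' @inheritParams runWorkloadPipeline
#' @return List with `summary` (data.frame: method, variant, selected_count,
#'   mean_acc_pct, sd_acc_pct), `curves` (named list of
#'   [AccuracyCurve-class]), and `consensus` (named list of
#'   [ConsensusResult-class]).
#' @export
compareRankers <- function(config = cohortConfig(),
                           protocol = evalProtocol(),
                           bands = bandsClassify3(), nBins = 5, topK = 10,
                           maxCurveFeatures = NULL, cohort = NULL) {
  if (is.null(cohort)) cohort <- generateCohort(config)
  tables <- lapply(cohort, subjectFeatureTable, bands = bands,
                   includeRatios = FALSE, preprocess = TRUE)
  methods <- c("jmi", "infogain", "ttest")
  curves <- list()
  consensi <- list()
  rows <- list()
  for (m in methods) {
    rankings <- lapply(tables, .rankTable, method = m, nBins = nBins)
    cons <- consensusScores(rankings, topK)
    consensi[[m]] <- cons
    mx <- if (is.null(maxCurveFeatures)) length(rankedFeatures(cons))
          else min(maxCurveFeatures, length(rankedFeatures(cons)))
    fsCurves <- mapply(function(tb, rk)
      accuracyCurve(tb, rk, protocol, maxFeatures = mx),
      tables, rankings, SIMPLIFY = FALSE)
    variants <- list(
      FS = grandAverageCurve(fsCurves),
      `FS+weights` = grandAverageCurve(
        lapply(tables, accuracyCurve, ranking = rankedFeatures(cons),
               protocol = protocol, maxFeatures = mx)))
    for (vn in names(variants)) {
      cu <- variants[[vn]]
      curves[[paste(m, vn, sep = "_")]] <- cu
      sel <- suppressWarnings(as.integer(stoppingCriterion(cu, protocol)))
      i <- match(sel, cu@featureCounts)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, variant = vn, selected_count = sel,
        mean_acc_pct = cu@meanAcc[i], sd_acc_pct = cu@sdAcc[i])
    }
  }
  list(summary = do.call(rbind, rows), curves = curves,
       consensus = consensi)
}
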