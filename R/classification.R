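#' @include AllClasses.R
NULL

# Stratified index split: per class, round(trainFraction * n) training rows.
.stratifiedSplit <- function(y, trainFraction) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    nTr <- max(1L, round(trainFraction * length(idx)))
    train <- c(train, sample(idx, nTr))
  }
  sort(train)
}

# LDA fit/predict accuracy (%) with zero-variance columns dropped and
# collinearity warnings silenced (LDA still predicts in that case).
.ldaAccuracy <- function(xtr, ytr, xte, yte) {
  keep <- apply(xtr, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) return(100 * max(table(yte)) / length(yte))
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  fit <- withCallingHandlers(
    MASS::lda(xtr, grouping = ytr),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pred <- stats::predict(fit, xte)$class
  100 * mean(pred == yte)
}

#' LDA evaluation of a feature subset
#'
#' Repeated stratified 70/30 splits: per repeat, an LDA is fitted on the
#' training portion (with an optional k-fold cross-validation sanity check)
#' and scored on the untouched held-out portion.  Reported as mean and
#' standard deviation (%) over `nRepeats` seeded splits, with the raw
#' per-repeat scores retained for the stopping t-tests.
#'
#' @param table a [FeatureTable-class].
#' @param features feature ids to use (default: all rows).
#' @param protocol an [EvalProtocol-class].
#' @param doCV also run the training-portion cross-validation.
#' @return List with `meanAcc`, `sdAcc`, `perRepeat`, `cvMeanAcc`.
#' @export
ldaEval <- function(table, features = NULL, protocol = evalProtocol(),
                    doCV = TRUE) {
  x <- t(SummarizedExperiment::assay(table, "values"))
  y <- factor(conditionLabels(table))
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing))
      stop("features not in table: ", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  counts <- table(y)
  starved <- names(counts)[round(counts * protocol@trainFraction) <
                             protocol@cvFolds]
  if (length(starved) && doCV)
    stop("class starvation: fewer training windows than cvFolds for ",
         paste(starved, collapse = ", "))
  if (any(counts < 2))
    stop("class starvation: fewer than 2 windows for ",
         paste(names(counts)[counts < 2], collapse = ", "))

  accs <- numeric(protocol@nRepeats)
  cvs <- rep(NA_real_, protocol@nRepeats)
  for (r in seq_len(protocol@nRepeats)) {
    withr::with_seed(protocol@seed + r - 1L, {
      tr <- .stratifiedSplit(y, protocol@trainFraction)
      xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
      xte <- x[-tr, , drop = FALSE]; yte <- y[-tr]
      accs[r] <- .ldaAccuracy(xtr, ytr, xte, yte)
      if (doCV) {
        folds <- integer(length(ytr))
        for (cl in levels(ytr)) {
          idx <- which(ytr == cl)
          folds[idx] <- sample(rep(seq_len(protocol@cvFolds),
                                   length.out = length(idx)))
        }
        cvAcc <- vapply(seq_len(protocol@cvFolds), function(k) {
          inK <- folds == k
          if (!any(inK) || all(inK)) return(NA_real_)
          .ldaAccuracy(xtr[!inK, , drop = FALSE], ytr[!inK],
                       xtr[inK, , drop = FALSE], ytr[inK])
        }, numeric(1))
        cvs[r] <- mean(cvAcc, na.rm = TRUE)
      }
    })
  }
  list(meanAcc = mean(accs), sdAcc = stats::sd(accs), perRepeat = accs,
       cvMeanAcc = mean(cvs))
}

#' Reference accuracies per single indicator
#'
#' Evaluates each of the six indicators (Theta, Alpha, Beta band powers and
#' the EI, TLI, TBR ratios) separately using its 14 channel features, giving
#' the per-indicator reference accuracy the ranked feature sets are compared
#' against.
#'
#' @param table a [FeatureTable-class] including ratio rows.
#' @param protocol an [EvalProtocol-class].
#' @param doCV also run the training-portion cross-validation.
#' @return data.frame with indicator, mean_acc_pct, sd_acc_pct.
#' @export
referenceAccuracies <- function(table, protocol = evalProtocol(),
                                doCV = FALSE) {
  rd <- SummarizedExperiment::rowData(table)
  indicators <- c("Theta", "Alpha", "Beta", "EI", "TLI", "TBR")
  res <- lapply(indicators, function(ind) {
    feats <- rownames(table)[rd$band == ind]
    if (!length(feats))
      stop("indicator ", ind, " is missing from the table")
    ev <- ldaEval(table, feats, protocol, doCV = doCV)
    data.frame(indicator = ind, mean_acc_pct = ev$meanAcc,
               sd_acc_pct = ev$sdAcc)
  })
  do.call(rbind, res)
}

#' Accuracy versus ranked-feature count
#'
#' Evaluates LDA on the prefix sets of a ranking (top 1, top 2, ...,
#' top `maxFeatures`) and returns the accuracy curve with per-repeat scores.
#'
#' @param table a [FeatureTable-class].
#' @param ranking a [FeatureRanking-class], [ConsensusResult-class] or
#'   character vector of ordered feature ids covering the table's features.
#' @param protocol an [EvalProtocol-class].
#' @param maxFeatures largest prefix evaluated (default: all ranked
#'   features).
#' @param doCV also run the training-portion cross-validation per count.
#' @return An [AccuracyCurve-class].
#' @export
accuracyCurve <- function(table, ranking, protocol = evalProtocol(),
                          maxFeatures = NULL, doCV = FALSE) {
  ordered <- if (is.character(ranking)) ranking else rankedFeatures(ranking)
  if (!all(ordered %in% rownames(table)))
    stop("ranking refers to features absent from the table")
  if (is.null(maxFeatures)) maxFeatures <- length(ordered)
  counts <- seq_len(maxFeatures)
  evs <- lapply(counts, function(k)
    ldaEval(table, ordered[seq_len(k)], protocol, doCV = doCV))
  new("AccuracyCurve", featureCounts = as.integer(counts),
      meanAcc = vapply(evs, `[[`, numeric(1), "meanAcc"),
      sdAcc = vapply(evs, `[[`, numeric(1), "sdAcc"),
      perRepeat = lapply(evs, `[[`, "perRepeat"),
      cvMeanAcc = vapply(evs, `[[`, numeric(1), "cvMeanAcc"))
}

# Two-sample t-test p-value robust to (near-)constant inputs.
.safeTP <- function(a, b) {
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
    return(if (abs(mean(a) - mean(b)) < 1e-9) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Stopping criterion on an accuracy curve
#'
#' Walks the feature counts in increasing order, comparing the per-repeat
#' held-out scores of consecutive counts with two-sample t-tests.  The
#' search stops when `consecutiveRequired` consecutive comparisons are all
#' non-significant at `alpha`; the selected count is the one producing the
#' first of those non-significant comparisons.  If no such run occurs the
#' maximum count is returned with a `"no plateau"` warning.
#'
#' @param curve an [AccuracyCurve-class] with per-repeat scores.
#' @param protocol an [EvalProtocol-class] (uses `alpha` and
#'   `consecutiveRequired`).
#' @return Selected feature count (integer) with attribute `pValues` (the
#'   step-wise t-test p-values).
#' @export
stoppingCriterion <- function(curve, protocol = evalProtocol()) {
  scores <- curve@perRepeat
  k <- length(scores)
  need <- protocol@consecutiveRequired
  if (k < need + 1)
    stop("curve needs at least consecutiveRequired + 1 points")
  pv <- vapply(seq_len(k - 1), function(i)
    .safeTP(scores[[i]], scores[[i + 1]]), numeric(1))
  ns <- pv >= protocol@alpha
  sel <- NA_integer_
  for (j in seq_len(length(ns) - need + 1)) {
    if (all(ns[j:(j + need - 1)])) { sel <- j; break }
  }
  if (is.na(sel)) {
    warning("no plateau: all consecutive comparisons stayed significant")
    out <- curve@featureCounts[k]
  } else {
    out <- curve@featureCounts[sel]
  }
  attr(out, "pValues") <- pv
  out
}

#' Grand-average accuracy curve across subjects
#'
#' Averages per-subject curves point-wise (repeat r of every subject is
#' aligned by the shared split seed), yielding the cohort-level curve the
#' stopping criterion is applied to.
#'
#' @param curves list of per-subject [AccuracyCurve-class] objects with
#'   identical feature counts.
#' @return An [AccuracyCurve-class].
#' @export
grandAverageCurve <- function(curves) {
  stopifnot(length(curves) >= 1)
  counts <- curves[[1]]@featureCounts
  for (cu in curves)
    if (!identical(cu@featureCounts, counts))
      stop("curves must share the same feature counts")
  perRepeat <- lapply(seq_along(counts), function(i) {
    rowMeans(vapply(curves, function(cu) cu@perRepeat[[i]],
                    numeric(length(curves[[1]]@perRepeat[[i]]))))
  })
  new("AccuracyCurve", featureCounts = counts,
      meanAcc = vapply(perRepeat, mean, numeric(1)),
      sdAcc = vapply(perRepeat, stats::sd, numeric(1)),
      perRepeat = perRepeat,
      cvMeanAcc = rowMeans(vapply(curves, function(cu) cu@cvMeanAcc,
                                  numeric(length(counts)))))
}
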