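#' @include AllClasses.R
NULL

#' Normality gate
#'
#' Shapiro-Wilk test on the pooled two-way residuals (subject and condition
#' effects removed).  If normality is rejected and all values are positive,
#' the data are log-transformed and retested.  The validation battery runs
#' nonparametrically either way — visual distributional judgment cannot be
#' automated faithfully — so the gate is evidence that is reported, not a
#' branch that changes the analysis.
#'
#' @param data a [RepeatedMeasures-class].
#' @param familyAlpha significance level of the gate (default 0.05).
#' @return List with `useNonparametric` (always `TRUE`), `transformed`,
#'   `pRaw`, `pLog`.
#' @export
normalityGate <- function(data, familyAlpha = 0.05) {
  v <- data@values
  resid <- v - rowMeans(v) -
    matrix(colMeans(v), nrow(v), ncol(v), byrow = TRUE) + mean(v)
  if (stats::sd(as.numeric(resid)) == 0)
    stop("Shapiro-Wilk is undefined for constant data")
  pRaw <- stats::shapiro.test(as.numeric(resid))$p.value
  pLog <- NA_real_
  transformed <- FALSE
  if (pRaw < familyAlpha) {
    if (all(v > 0)) {
      lv <- log(v)
      lresid <- lv - rowMeans(lv) -
        matrix(colMeans(lv), nrow(lv), ncol(lv), byrow = TRUE) + mean(lv)
      pLog <- stats::shapiro.test(as.numeric(lresid))$p.value
      transformed <- TRUE
    } else {
      warning("non-positive values: log transform skipped")
    }
  }
  list(useNonparametric = TRUE, transformed = transformed,
       pRaw = pRaw, pLog = pLog)
}

#' Friedman repeated-measures test
#'
#' Within-subject mid-ranks, chi-squared statistic with `k - 1` degrees of
#' freedom (tie-corrected) and asymptotic p-value.  Fully tied rows
#' degenerate to `chi2 = 0, p = 1`.
#'
#' @param data a [RepeatedMeasures-class] (>= 2 subjects, >= 2 conditions).
#' @return List with `chi2`, `df`, `p`.
#' @export
friedmanTest <- function(data) {
  v <- data@values
  n <- nrow(v); k <- ncol(v)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  r <- t(apply(v, 1, rank))                         # mid-ranks for ties
  colSumsR <- colSums(r)
  num <- 12 * sum((colSumsR - n * (k + 1) / 2)^2)
  tieTerm <- sum(apply(r, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })) / (k - 1)
  den <- n * k * (k + 1) - tieTerm
  chi2 <- if (den <= 0) 0 else num / den
  p <- if (den <= 0) 1 else stats::pchisq(chi2, k - 1, lower.tail = FALSE)
  list(chi2 = chi2, df = k - 1, p = p)
}

#' Pairwise Wilcoxon signed-rank post-hoc tests
#'
#' All `choose(k, 2)` two-sided paired signed-rank tests (asymptotic
#' p-values with continuity correction, zero differences dropped) against
#' the Bonferroni-corrected threshold `familyAlpha / choose(k, 2)` — 0.0083
#' for four conditions at a family alpha of 0.05.
#'
#' @param data a [RepeatedMeasures-class].
#' @param familyAlpha family-wise significance level (default 0.05).
#' @return List with `posthoc` (data.frame pair, p, significant) and
#'   `bonferroniAlpha`.
#' @export
wilcoxonPosthoc <- function(data, familyAlpha = 0.05) {
  v <- data@values
  k <- ncol(v)
  pairs <- utils::combn(k, 2)
  labels <- data@conditionLabels
  res <- apply(pairs, 2, function(pr) {
    a <- v[, pr[1]]; b <- v[, pr[2]]
    if (all(a == b)) {
      warning("all-zero difference vector for ", labels[pr[1]], " vs ",
              labels[pr[2]], "; p set to 1")
      return(1)
    }
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                       correct = TRUE)$p.value
  })
  threshold <- familyAlpha / ncol(pairs)
  posthoc <- data.frame(
    pair = apply(pairs, 2, function(pr)
      paste(labels[pr[1]], "vs", labels[pr[2]])),
    p = as.numeric(res),
    significant = as.numeric(res) < threshold)
  list(posthoc = posthoc, bonferroniAlpha = threshold)
}

#' Aggregate the consensus EEG features to one scalar per subject-condition
#'
#' Per subject and condition, the mean over all windows and over the
#' selected features of the baseline-relative power — the scalar entering
#' the repeated-measures validation of the proposed EEG indicator set.
#'
#' @param tables list of per-subject [FeatureTable-class] objects.
#' @param featureSet non-empty character vector of consensus feature ids.
#' @param conditions condition order for the columns.
#' @return A [RepeatedMeasures-class] with `metricName = "EEG"`.
#' @export
aggregateEegMetric <- function(tables, featureSet,
                               conditions = WORKLOAD_CONDITIONS) {
  if (!length(featureSet)) stop("featureSet must be non-empty")
  cells <- t(vapply(tables, function(tb) {
    v <- SummarizedExperiment::assay(tb, "values")[featureSet, ,
                                                   drop = FALSE]
    y <- conditionLabels(tb)
    vapply(conditions, function(cd) mean(v[, y == cd, drop = FALSE]),
           numeric(1))
  }, numeric(length(conditions))))
  rownames(cells) <- vapply(tables, function(tb) subjectId(tb)[1],
                            character(1))
  repeatedMeasures(cells, "EEG", conditions)
}

#' Repeated-measures matrices for the subjective and physiological metrics
#'
#' Per subject and condition: the mean subjective-workload response over
#' repetitions (`atwitMeasures`) and the mean heart rate over the trials'
#' samples (`hrMeasures`).
#'
#' @param cohort list of [SubjectDataset-class] objects.
#' @param conditions condition order for the columns.
#' @return A [RepeatedMeasures-class].
#' @export
atwitMeasures <- function(cohort, conditions = WORKLOAD_CONDITIONS) {
  cells <- t(vapply(cohort, function(sd) {
    vapply(conditions, function(cd)
      mean(sd@atwitScores[sd@trialInfo$condition == cd]), numeric(1))
  }, numeric(length(conditions))))
  rownames(cells) <- vapply(cohort, subjectId, character(1))
  repeatedMeasures(cells, "ATWIT", conditions)
}

#' @rdname atwitMeasures
#' @export
hrMeasures <- function(cohort, conditions = WORKLOAD_CONDITIONS) {
  cells <- t(vapply(cohort, function(sd) {
    vapply(conditions, function(cd)
      mean(unlist(sd@hrSeries[sd@trialInfo$condition == cd])), numeric(1))
  }, numeric(length(conditions))))
  rownames(cells) <- vapply(cohort, subjectId, character(1))
  repeatedMeasures(cells, "HR", conditions)
}

#' Full validation battery for one metric
#'
#' Normality gate, Friedman omnibus test and Bonferroni-corrected Wilcoxon
#' signed-rank post-hoc tests, assembled into a [ValidationReport-class].
#'
#' @param data a [RepeatedMeasures-class].
#' @param familyAlpha family-wise significance level (default 0.05).
#' @return A [ValidationReport-class].
#' @export
validateMetric <- function(data, familyAlpha = 0.05) {
  gate <- tryCatch(normalityGate(data, familyAlpha), error = function(e) {
    warning("normality gate unavailable (", conditionMessage(e),
            "); proceeding nonparametrically")
    list(useNonparametric = TRUE, transformed = FALSE, pRaw = NA_real_,
         pLog = NA_real_)
  })
  fr <- friedmanTest(data)
  ph <- wilcoxonPosthoc(data, familyAlpha)
  new("ValidationReport", metricName = data@metricName,
      normalityP = gate$pRaw, normalityPLog = gate$pLog,
      transformed = gate$transformed,
      useNonparametric = gate$useNonparametric,
      friedmanChi2 = fr$chi2, friedmanP = fr$p, posthoc = ph$posthoc,
      bonferroniAlpha = ph$bonferroniAlpha)
}

#' Condition-level summary (mean and sd) of a repeated-measures metric
#'
#' @param data a [RepeatedMeasures-class].
#' @return data.frame with condition, mean, sd.
#' @export
conditionSummary <- function(data) {
  data.frame(condition = data@conditionLabels,
             mean = as.numeric(colMeans(data@values)),
             sd = as.numeric(apply(data@values, 2, stats::sd)))
}
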