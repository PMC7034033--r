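#' @include AllClasses.R
NULL

#' Equal-frequency discretization
#'
#' Quantile (equal-frequency) binning used by the mutual-information
#' estimator: with distinct values the bin populations differ by at most
#' one.  A constant column collapses to a single bin with a warning.
#'
#' @param values numeric vector.
#' @param nBins number of bins (>= 2).
#' @return Integer vector of bin indices in `1..nBins`.
#' @export
discretizeFeature <- function(values, nBins = 5) {
  stopifnot(nBins >= 2)
  if (diff(range(values)) == 0) {
    warning("constant column: single-bin discretization")
    return(rep(1L, length(values)))
  }
  r <- rank(values, ties.method = "first")
  as.integer(floor((r - 1) * nBins / length(values)) + 1L)
}

#' Plug-in mutual information (bits)
#'
#' `I(X; Y) = sum p(x, y) log2[p(x, y) / (p(x) p(y))]` over the empirical
#' joint distribution of two discrete columns.
#'
#' @param x,y discrete vectors of equal length.
#' @return Mutual information in bits (>= 0).
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

# Discretize every feature of a table; rows = windows, columns = features,
# features in lexicographic id order for deterministic tie-breaking.
.discretizeTable <- function(table, nBins) {
  v <- t(SummarizedExperiment::assay(table, "values"))
  v <- v[, order(colnames(v)), drop = FALSE]
  d <- apply(v, 2, discretizeFeature, nBins = nBins)
  storage.mode(d) <- "integer"
  d
}

.classLabels <- function(table) {
  y <- conditionLabels(table)
  if (is.null(y) || any(is.na(y))) stop("condition labels are missing")
  as.integer(factor(y))
}

#' Joint-mutual-information feature ranking
#'
#' Greedy forward selection: the first feature maximizes `I(X; Y)`; every
#' subsequent feature `f` maximizes the JMI criterion
#' `sum over selected s of I((X_f, X_s); Y)`, where `(X_f, X_s)` is the
#' pairwise joint variable.  The full ranking of all features is returned;
#' stored scores are the per-step criterion values.  Ties are broken by
#' lexicographic feature id, so the ranking is deterministic.
#'
#' @param table a [FeatureTable-class] with condition labels.
#' @param nBins equal-frequency bins for the mutual-information estimate.
#' @return A [FeatureRanking-class] with `method = "JMI"`.
#' @export
jmiRank <- function(table, nBins = 5) {
  if (nrow(table) < 2) stop("at least 2 features are required")
  y <- .classLabels(table)
  d <- .discretizeTable(table, nBins)
  ids <- colnames(d)
  p <- length(ids)
  relevance <- vapply(seq_len(p), function(j) mutualInformation(d[, j], y),
                      numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  cum <- rep(0, p)                 # sum over selected of I((Xf, Xs); Y)
  first <- remaining[which.max(relevance[remaining])]
  selected <- first
  scores <- relevance[first]
  remaining <- setdiff(remaining, first)
  while (length(remaining)) {
    s <- selected[length(selected)]
    for (f in remaining) {
      jointVar <- (d[, f] - 1L) * nBins + d[, s]
      cum[f] <- cum[f] + mutualInformation(jointVar, y)
    }
    best <- remaining[which.max(cum[remaining])]
    selected <- c(selected, best)
    scores <- c(scores, cum[best])
    remaining <- setdiff(remaining, best)
  }
  FeatureRanking(subjectId(table)[1], "JMI", ids[selected], scores)
}

#' Information-gain feature ranking
#'
#' Univariate `I(X_f; Y)` per feature, sorted descending; ties broken by
#' feature id.  Coincides with the first step of the JMI criterion.
#'
#' @inheritParams jmiRank
#' @return A [FeatureRanking-class] with `method = "InfoGain"`.
#' @export
infoGainRank <- function(table, nBins = 5) {
  y <- .classLabels(table)
  d <- .discretizeTable(table, nBins)
  ig <- vapply(seq_len(ncol(d)), function(j) mutualInformation(d[, j], y),
               numeric(1))
  ord <- order(-ig, colnames(d))
  FeatureRanking(subjectId(table)[1], "InfoGain", colnames(d)[ord], ig[ord])
}

# Pooled-variance two-sample t statistic, vectorised over feature columns.
.pooledT <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  va <- apply(xa, 2, stats::var)
  vb <- apply(xb, 2, stats::var)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  (colMeans(xa) - colMeans(xb)) / (sp * sqrt(1 / na + 1 / nb))
}

#' Two-sample t-statistic feature ranking
#'
#' Scores each feature by the absolute pooled-variance two-sample t
#' statistic contrasting the two extreme conditions (first vs last condition
#' label, i.e. lowest vs highest workload), sorted descending.
#'
#' @param table a [FeatureTable-class] with the four condition labels.
#' @return A [FeatureRanking-class] with `method = "TStat"`.
#' @export
tTestRank <- function(table) {
  y <- conditionLabels(table)
  conds <- if (all(y %in% WORKLOAD_CONDITIONS)) WORKLOAD_CONDITIONS
           else unique(y)
  lowC <- conds[1]
  highC <- conds[length(conds)]
  v <- t(SummarizedExperiment::assay(table, "values"))
  v <- v[, order(colnames(v)), drop = FALSE]
  xa <- v[y == highC, , drop = FALSE]
  xb <- v[y == lowC, , drop = FALSE]
  if (nrow(xa) < 2 || nrow(xb) < 2)
    stop("each extreme condition needs at least 2 windows (",
         lowC, " vs ", highC, ")")
  tt <- abs(.pooledT(xa, xb))
  ord <- order(-tt, colnames(v))
  FeatureRanking(subjectId(table)[1], "TStat", colnames(v)[ord], tt[ord])
}

#' Correlation screen for ratio features
#'
#' Pearson correlations over all features; a ratio feature is flagged for
#' exclusion when its absolute correlation with any of its parent band
#' features (same channel, the bands entering the ratio) exceeds the
#' threshold.  Returns the correlation matrix, the flagged features, and the
#' band-only table.
#'
#' @param table a [FeatureTable-class] including ratio rows.
#' @param threshold absolute-correlation threshold (default 0.8).
#' @return List with `correlations`, `excluded` (data.frame feature, parent,
#'   r), and `screened` (band-power-only [FeatureTable-class]).
#' @export
correlationScreen <- function(table, threshold = 0.8) {
  v <- t(SummarizedExperiment::assay(table, "values"))
  cc <- stats::cor(v)
  rd <- SummarizedExperiment::rowData(table)
  parents <- list(EI = c("Beta", "Alpha", "Theta"),
                  TLI = c("Theta", "Alpha"), TBR = c("Theta", "Beta"))
  excluded <- data.frame(feature = character(0), parent = character(0),
                         r = numeric(0))
  ratioRows <- which(rd$type == "ratio")
  for (i in ratioRows) {
    fid <- rownames(table)[i]
    par <- paste0(parents[[rd$band[i]]], rd$channel[i])
    par <- par[par %in% rownames(table)]
    if (!length(par)) next
    r <- cc[fid, par]
    j <- which.max(abs(r))
    if (abs(r[j]) > threshold)
      excluded <- rbind(excluded, data.frame(feature = fid,
                                             parent = par[j], r = r[j]))
  }
  list(correlations = cc, excluded = excluded, screened = bandOnly(table))
}
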