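#' @include AllClasses.R
NULL

#' Rank-position weight
#'
#' Affine weight for a feature occupying a 1-based position in a subject's
#' top-k list: position 1 weighs 1.0, each later position 0.1 less, down to
#' 0.1 at position 10 (`weight = 1 - 0.1 * (position - 1)`).  For pooling
#' depths other than 10 the same endpoints (1.0 down to 0.1) are
#' interpolated linearly over the available positions.
#'
#' @param position 1-based rank position(s).
#' @param topK pooling depth the weights span (default 10).
#' @return Numeric weight(s).
#' @export
positionWeight <- function(position, topK = 10) {
  if (any(position < 1 | position > topK) || any(position != round(position)))
    stop("position must be an integer in [1, ", topK, "]")
  if (topK == 1) return(rep(1, length(position)))
  if (topK == 10) (11 - position) / 10          # exact decimal weights
  else 1 - 0.9 * (position - 1) / (topK - 1)
}

#' Pool per-subject rankings into consensus scores
#'
#' Takes the top `topK` features from every subject's ranking (a pooled list
#' of `n_subjects * topK` entries), counts each feature's appearances and
#' sums its rank-position weights: a feature at position 1 for one subject
#' and position 7 for another (absent elsewhere) scores `1.0 + 0.4 = 1.4`.
#' Features never appearing in any top-k list score 0 and are excluded from
#' the scored head of the ordering.
#'
#' @param rankings list of [FeatureRanking-class] covering the same feature
#'   universe.
#' @param topK pooling depth (default 10).
#' @return A [ConsensusResult-class].
#' @export
consensusScores <- function(rankings, topK = 10) {
  stopifnot(length(rankings) >= 1)
  universe <- sort(rankedFeatures(rankings[[1]]))
  for (r in rankings)
    if (!identical(sort(rankedFeatures(r)), universe))
      stop("rankings cover inconsistent feature universes")
  if (topK > length(universe))
    stop("topK exceeds the feature universe size")
  scores <- stats::setNames(numeric(length(universe)), universe)
  counts <- stats::setNames(integer(length(universe)), universe)
  for (r in rankings) {
    top <- rankedFeatures(r)[seq_len(topK)]
    scores[top] <- scores[top] + positionWeight(seq_len(topK), topK)
    counts[top] <- counts[top] + 1L
  }
  # scores are sums of multiples of 0.1; snap to that grid so the ordering
  # is independent of floating-point accumulation order (subject symmetry)
  scores <- round(scores * 10) / 10
  keep <- counts >= 1L
  ord <- order(-scores[keep], -counts[keep], universe[keep])
  ordered <- universe[keep][ord]
  new("ConsensusResult", scores = scores[ordered],
      appearanceCounts = counts[ordered], orderedFeatures = ordered,
      pooledListSize = as.integer(length(rankings) * topK),
      topK = as.integer(topK), nSubjects = as.integer(length(rankings)),
      featureUniverse = universe)
}

#' Select the consensus top set
#'
#' First `nFeatures` of the consensus ordering; ties are already resolved by
#' (higher appearance count, then feature id).
#'
#' @param result a [ConsensusResult-class].
#' @param nFeatures number of features to keep (at most the number of scored
#'   features).
#' @return Character vector of feature ids.
#' @export
selectTopSet <- function(result, nFeatures) {
  if (nFeatures > length(result@orderedFeatures))
    stop("nFeatures exceeds the number of scored features")
  result@orderedFeatures[seq_len(nFeatures)]
}

#' Consensus result as a data.frame
#'
#' @param result a [ConsensusResult-class].
#' @return data.frame with feature_id, appearances, score, final_rank.
#' @export
consensusTable <- function(result) {
  data.frame(feature_id = result@orderedFeatures,
             appearances = as.integer(result@appearanceCounts),
             score = as.numeric(result@scores),
             final_rank = seq_along(result@orderedFeatures))
}
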