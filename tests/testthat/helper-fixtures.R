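# Shared fixtures and independent oracles.  Oracles are written as plainly
# as possible (loops, direct formulas) and never call the implementation
# they are used to check.

# Small, fast cohort configuration: full condition structure, short trials.
smallConfig <- function(nSubjects = 2, trialSeconds = 40,
                        baselineSeconds = 30, seed = 1L, ...) {
  cohortConfig(nSubjects = nSubjects, trialSeconds = trialSeconds,
               baselineSeconds = baselineSeconds, seed = seed, ...)
}

# Sinusoid recording: one or more channels of a_i * sin(2 pi f_i t) + c_i.
sineRecording <- function(freqs, amps = rep(1, length(freqs)),
                          offsets = rep(0, length(freqs)), seconds = 20,
                          fs = 128, labels = paste0("ch", seq_along(freqs)),
                          condition = NA_character_) {
  t <- (0:(seconds * fs - 1)) / fs
  dat <- t(mapply(function(f, a, c) a * sin(2 * pi * f * t) + c,
                  freqs, amps, offsets))
  EEGRecording(dat, fs, labels, condition = condition)
}

# Feature table built directly from a windows x features matrix.
toyTable <- function(values, condition, subjectId = "S1",
                     band = NULL, channel = NULL, type = NULL) {
  m <- t(values)                                  # features x windows
  p <- nrow(m)
  if (is.null(band)) band <- rep("Beta", p)
  if (is.null(channel)) channel <- paste0("C", seq_len(p))
  if (is.null(type)) type <- rep("synthetic", p)   # skip positivity check
  if (is.null(rownames(m))) rownames(m) <- paste0(band, channel)
  FeatureTable(m, channel = channel, band = band, type = type,
               condition = condition, subjectId = subjectId)
}

# --- Oracles ---------------------------------------------------------------

# Mutual information in bits by direct double summation over the joint table.
oracleMI <- function(x, y) {
  n <- length(x)
  tot <- 0
  for (xv in unique(x)) for (yv in unique(y)) {
    pxy <- sum(x == xv & y == yv) / n
    if (pxy == 0) next
    px <- sum(x == xv) / n
    py <- sum(y == yv) / n
    tot <- tot + pxy * log2(pxy / (px * py))
  }
  tot
}

# Greedy JMI ranking by brute-force evaluation of the criterion at every
# step: candidate f scores sum over selected s of I((Xf, Xs); Y).
oracleJMI <- function(d, y, nBins) {
  p <- ncol(d)
  ids <- colnames(d)
  rel <- vapply(seq_len(p), function(j) oracleMI(d[, j], y), numeric(1))
  sel <- which.max(rel)
  remaining <- setdiff(seq_len(p), sel)
  while (length(remaining)) {
    crit <- vapply(remaining, function(f) {
      sum(vapply(sel, function(s)
        oracleMI(paste(d[, f], d[, s]), y), numeric(1)))
    }, numeric(1))
    sel <- c(sel, remaining[which.max(crit)])
    remaining <- setdiff(remaining, sel)
  }
  ids[sel]
}

# Friedman chi-squared with mid-ranks and tie correction, step by step.
oracleFriedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- matrix(0, n, k)
  for (i in seq_len(n)) r[i, ] <- rank(m[i, ])
  Rj <- colSums(r)
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  ties <- 0
  for (i in seq_len(n)) {
    tt <- table(r[i, ])
    ties <- ties + sum(tt^3 - tt)
  }
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 0) 0 else num / den
}

# Wilcoxon signed-rank statistic V (sum of positive-difference ranks,
# zero differences dropped).
oracleSignedRankV <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

DEFAULT_FEATURES <- paste0(rep(c("Theta", "Alpha", "Beta"), each = 14),
                           rep(eegworkload:::EMOTIV_MONTAGE, 3))

# A ranking placing `top` first, the rest of the universe in the given order.
rankingWith <- function(top, universe = DEFAULT_FEATURES, subjectId = "S1",
                        method = "InfoGain") {
  ordered <- c(top, setdiff(universe, top))
  FeatureRanking(subjectId, method, ordered,
                 scores = rev(seq_along(ordered)))
}
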