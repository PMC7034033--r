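#' @include AllClasses.R
NULL

#' Windowed Hamming periodogram
#'
#' Splits each channel into `windowSeconds` windows with the given overlap,
#' applies a Hamming taper and returns one-sided FFT periodograms with
#' energy normalization, so that the integral of the PSD over frequency
#' equals the window's mean power (Parseval).  Windows containing any masked
#' sample are dropped.
#'
#' @param rec an [EEGRecording-class].
#' @param windowSeconds window length in seconds (default 10; frequency
#'   resolution `1/windowSeconds`).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return List with `freq` (Hz), `psd` (array window x channel x frequency,
#'   uV^2/Hz), `windowStarts` (s) and `fs`.
#' @export
windowedPsd <- function(rec, windowSeconds = 10, overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1)
  fs <- rec@fs
  n <- ncol(rec@data)
  w <- round(windowSeconds * fs)
  if (w > n) stop("no usable windows: recording shorter than one window")
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, n - w + 1L, by = step)
  usable <- vapply(starts, function(s)
    !any(rec@artifactMask[s:(s + w - 1L)]), logical(1))
  if (!any(usable)) stop("no usable windows: all windows overlap artifacts")
  starts <- starts[usable]
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  U <- sum(ham^2)
  nf <- floor(w / 2) + 1L
  freq <- (0:(nf - 1)) * fs / w
  psd <- array(0, c(length(starts), nrow(rec@data), nf))
  oneSided <- c(1, rep(2, nf - 2), if (w %% 2 == 0) 1 else 2)
  for (ci in seq_len(nrow(rec@data))) {
    for (wi in seq_along(starts)) {
      seg <- rec@data[ci, starts[wi]:(starts[wi] + w - 1L)] * ham
      X <- stats::fft(seg)[seq_len(nf)]
      psd[wi, ci, ] <- oneSided * (Mod(X)^2) / (fs * U)
    }
  }
  dimnames(psd) <- list(NULL, rec@channelLabels, NULL)
  list(freq = freq, psd = psd, windowStarts = (starts - 1) / fs, fs = fs)
}

#' Band power from a windowed PSD
#'
#' Rectangle-rule integral of the PSD over the half-open interval
#' `[low, high)` Hz.
#'
#' @param psd result of [windowedPsd()].
#' @param lowHz,highHz band edges (Hz); must lie within the PSD range.
#' @return windows x channels matrix of band power (uV^2).
#' @export
bandPower <- function(psd, lowHz, highHz) {
  if (lowHz < min(psd$freq) || highHz > max(psd$freq) + 1e-9)
    stop("band outside the PSD frequency range")
  df <- psd$freq[2] - psd$freq[1]
  sel <- which(psd$freq >= lowHz & psd$freq < highHz)
  out <- apply(psd$psd[, , sel, drop = FALSE], c(1, 2), sum) * df
  matrix(out, nrow = dim(psd$psd)[1], ncol = dim(psd$psd)[2],
         dimnames = list(NULL, dimnames(psd$psd)[[2]]))
}

#' Baseline-relative power normalization
#'
#' Divides each window's band power by the same subject's same-(channel,
#' band) power from the resting baseline recording, yielding unitless
#' relative powers comparable across channels and bands.
#'
#' @param trialBandPowers windows x channels matrix of band power.
#' @param baselineBandPowers per-channel baseline band power (same band).
#' @return windows x channels matrix of relative power.
#' @export
relativeNormalize <- function(trialBandPowers, baselineBandPowers) {
  if (any(!is.finite(baselineBandPowers)) || any(baselineBandPowers <= 0))
    stop("baseline power must be positive for normalization")
  sweep(trialBandPowers, 2, baselineBandPowers, "/")
}

#' Ratio workload indices
#'
#' Engagement index `EI = beta / (alpha + theta)`, task-load index
#' `TLI = theta / alpha` and theta/beta ratio `TBR = theta / beta`, all
#' invariant to common scaling of the three band powers.
#'
#' @param theta,alpha,beta band powers (all strictly positive; vectors or
#'   matrices of matching shape).
#' @return List with elements `EI`, `TLI`, `TBR`.
#' @export
ratioIndices <- function(theta, alpha, beta) {
  if (any(theta <= 0) || any(alpha <= 0) || any(beta <= 0))
    stop("band powers must be strictly positive")
  list(EI = beta / (alpha + theta), TLI = theta / alpha, TBR = theta / beta)
}

#' Extract spectral workload features from one recording
#'
#' Windowed band powers normalized to the subject's baseline recording
#' (feature ids `<Band><Channel>`, e.g. `BetaT7`), plus optional ratio
#' indices (`EI`, `TLI`, `TBR` per channel, computed from the absolute
#' theta/alpha/beta powers).  Every window inherits the trial's condition
#' label.
#'
#' @param rec trial [EEGRecording-class].
#' @param baseline the same subject's baseline [EEGRecording-class]
#'   (identical montage).
#' @param bands band set (data.frame name/low/high); see [bandsClassify3()].
#' @param includeRatios add the three ratio indices per channel.
#' @param windowSeconds,overlap windowing parameters.
#' @param normalize `"baseline"` (divide by baseline band power) or
#'   `"broadband"` (divide by the window's own total power).
#' @return A [FeatureTable-class] with `channels x (bands + ratios)` rows.
#' @export
extractFeatures <- function(rec, baseline, bands = bandsClassify3(),
                            includeRatios = FALSE, windowSeconds = 10,
                            overlap = 0.5,
                            normalize = c("baseline", "broadband")) {
  normalize <- match.arg(normalize)
  if (!identical(rec@channelLabels, baseline@channelLabels))
    stop("trial and baseline recordings must share the same montage")
  psdT <- windowedPsd(rec, windowSeconds, overlap)
  nWin <- dim(psdT$psd)[1]
  chs <- rec@channelLabels

  absPow <- lapply(seq_len(nrow(bands)), function(bi)
    bandPower(psdT, bands$low[bi], bands$high[bi]))
  names(absPow) <- bands$name

  if (normalize == "baseline") {
    psdB <- windowedPsd(baseline, windowSeconds, overlap)
    rel <- lapply(seq_len(nrow(bands)), function(bi) {
      bb <- colMeans(bandPower(psdB, bands$low[bi], bands$high[bi]))
      relativeNormalize(absPow[[bi]], bb)
    })
  } else {
    total <- bandPower(psdT, min(bands$low), max(bands$high))
    rel <- lapply(absPow, function(bp) bp / total)
  }
  names(rel) <- bands$name

  blocks <- list()
  meta <- list()
  for (bi in seq_len(nrow(bands))) {
    m <- t(rel[[bi]])                              # channels x windows
    rownames(m) <- paste0(bands$name[bi], chs)
    blocks[[length(blocks) + 1L]] <- m
    meta[[length(meta) + 1L]] <- data.frame(channel = chs,
                                            band = bands$name[bi],
                                            type = "power")
  }
  if (includeRatios) {
    need <- c("Theta", "Alpha", "Beta")
    if (!all(need %in% names(absPow)))
      stop("ratio indices require Theta, Alpha and Beta bands")
    ri <- ratioIndices(absPow$Theta, absPow$Alpha, absPow$Beta)
    for (nm in names(ri)) {
      m <- t(ri[[nm]])
      rownames(m) <- paste0(nm, chs)
      blocks[[length(blocks) + 1L]] <- m
      meta[[length(meta) + 1L]] <- data.frame(channel = chs, band = nm,
                                              type = "ratio")
    }
  }
  values <- do.call(rbind, blocks)
  meta <- do.call(rbind, meta)
  FeatureTable(values, channel = meta$channel, band = meta$band,
               type = meta$type,
               condition = rep(rec@condition, nWin),
               windowStart = psdT$windowStarts,
               subjectId = rec@subjectId,
               repetition = rep(rec@repetition, nWin))
}

#' Per-subject feature table across all trials
#'
#' Optionally preprocesses every recording, extracts features per trial and
#' concatenates the windows into one [FeatureTable-class].
#'
#' @param subject a [SubjectDataset-class].
#' @param bands band set.
#' @param includeRatios add ratio indices.
#' @param preprocess run [preprocessRecording()] on each recording first.
#' @param windowSeconds,overlap windowing parameters.
#' @param ... further arguments to [preprocessRecording()].
#' @return A [FeatureTable-class] whose columns span all trials.
#' @export
subjectFeatureTable <- function(subject, bands = bandsClassify3(),
                                includeRatios = FALSE, preprocess = TRUE,
                                windowSeconds = 10, overlap = 0.5, ...) {
  if (preprocess) subject <- preprocessSubject(subject, ...)
  base <- subject@baseline
  tabs <- lapply(subject@trials, extractFeatures, baseline = base,
                 bands = bands, includeRatios = includeRatios,
                 windowSeconds = windowSeconds, overlap = overlap)
  do.call(BiocGenerics::cbind, tabs)
}

#' Restrict a feature table to band-power features
#'
#' @param table a [FeatureTable-class].
#' @return The table without ratio rows.
#' @export
bandOnly <- function(table) {
  table[SummarizedExperiment::rowData(table)$type == "power", ]
}
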