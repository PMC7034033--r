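#' @include AllClasses.R
NULL

#' Pretrial baseline correction
#'
#' Subtracts, per channel, the mean of the leading `pretrialMs` milliseconds
#' from the whole channel.
#'
#' @param rec an [EEGRecording-class].
#' @param pretrialMs pretrial window length in ms (default 200).
#' @return The corrected recording.
#' @export
baselineCorrect <- function(rec, pretrialMs = 200) {
  nPre <- round(pretrialMs / 1000 * rec@fs)
  if (nPre < 1 || nPre >= ncol(rec@data))
    stop("recording is shorter than the pretrial window")
  mu <- rowMeans(rec@data[, seq_len(nPre), drop = FALSE])
  out <- rec
  out@data <- rec@data - mu
  out
}

# Zero-phase band-pass: linear-phase Hamming-window FIR (signal::fir1), whose
# constant group delay of order/2 samples is compensated exactly after a
# single reflected-padding FFT convolution.  Single-pass stopband attenuation
# at the design order exceeds 50 dB one octave below the low edge.
.firBandpass <- function(x, fs, low, high, order) {
  b <- as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass"))
  half <- order / 2
  n <- length(x)
  pad <- min(order, n - 1)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- stats::convolve(xp, rev(b), type = "open")
  y[(pad + half + 1):(pad + half + n)]
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase FIR band-pass (Hamming-window design) with exact
#' group-delay compensation, so filtered samples stay aligned with the raw
#' recording and window boundaries are preserved.  Default band 2-43 Hz.
#'
#' @param rec an [EEGRecording-class].
#' @param lowHz,highHz band edges in Hz; `0 < lowHz < highHz < fs/2`.
#' @param order FIR order (even; default 512 taps + 1 at 128 Hz, scaled with
#'   the sampling rate).
#' @return The filtered recording (same fs, channels, labels).
#' @export
bandpassFir <- function(rec, lowHz = 2, highHz = 43, order = NULL) {
  if (lowHz <= 0 || lowHz >= highHz || highHz >= rec@fs / 2)
    stop("band edges must satisfy 0 < lowHz < highHz < fs/2")
  if (is.null(order)) order <- 2 * round(2 * rec@fs)      # 512 at 128 Hz
  if (order %% 2 == 1) order <- order + 1
  out <- rec
  out@data <- t(apply(rec@data, 1, .firBandpass, fs = rec@fs,
                      low = lowHz, high = highHz, order = order))
  rownames(out@data) <- rec@channelLabels
  out
}

#' Robust spike gating
#'
#' Marks samples whose robust z-score (per-channel median/MAD) exceeds
#' `kSigma` in the artifact mask, padding by `padMs` on each side; masked
#' samples are excluded from subsequent windowing.  An automated stand-in for
#' manual removal of large electrode-movement spikes.
#'
#' @param rec an [EEGRecording-class].
#' @param kSigma robust z threshold (default 8).
#' @param padMs padding around each detection, ms, each side (default 200).
#' @return The recording with an updated artifact mask (data unchanged).
#' @export
gateSpikes <- function(rec, kSigma = 8, padMs = 200) {
  stopifnot(kSigma > 0)
  n <- ncol(rec@data)
  pad <- round(padMs / 1000 * rec@fs)
  hit <- rep(FALSE, n)
  for (ci in seq_len(nrow(rec@data))) {
    x <- rec@data[ci, ]
    s <- stats::mad(x)
    if (s == 0) next
    z <- abs(x - stats::median(x)) / s
    hit <- hit | (z > kSigma)
  }
  if (any(hit)) {
    idx <- which(hit)
    lo <- pmax(1L, idx - pad)
    hi <- pmin(n, idx + pad)
    for (i in seq_along(idx)) hit[lo[i]:hi[i]] <- TRUE
  }
  out <- rec
  out@artifactMask <- rec@artifactMask | hit
  out
}

#' Frontal-reference blink suppression
#'
#' Builds a blink reference as the 0.5-4 Hz component of the mean of the
#' frontal channels and regresses it out of every channel (least squares on
#' the centered reference), so per-channel output variance never exceeds
#' input variance.  A simplified, documented stand-in for ICA-based artifact
#' classification, which is out of scope.
#'
#' @param rec an [EEGRecording-class].
#' @param templateBandHz low/high band of the blink reference, Hz.
#' @param frontalChannels labels averaged into the reference.
#' @return The cleaned recording.
#' @export
suppressBlinks <- function(rec, templateBandHz = c(0.5, 4),
                           frontalChannels = c("AF3", "AF4", "F7", "F8")) {
  present <- frontalChannels %in% rec@channelLabels
  if (!all(present))
    stop("missing frontal channels: ",
         paste(frontalChannels[!present], collapse = ", "))
  frontal <- colMeans(rec@data[match(frontalChannels, rec@channelLabels), ,
                               drop = FALSE])
  ref <- .fftBandpass(frontal, rec@fs, templateBandHz[1], templateBandHz[2])
  ref <- ref - mean(ref)
  denom <- sum(ref^2)
  out <- rec
  if (denom > 0) {
    beta <- as.numeric(rec@data %*% ref) / denom
    out@data <- rec@data - outer(beta, ref)
  }
  out
}

# Ideal (brick-wall) FFT band-pass used for the blink reference and for
# band-limited RMS measurements; half-open band [low, high).
.fftBandpass <- function(x, fs, low, high) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  X <- stats::fft(x)
  keepPos <- freqs >= low & freqs < high & freqs <= fs / 2
  keepNeg <- (fs - freqs) >= low & (fs - freqs) < high & freqs > fs / 2
  X[!(keepPos | keepNeg)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Full preprocessing chain
#'
#' Baseline correction, 2-43 Hz zero-phase FIR band-pass, robust spike
#' gating, then frontal-reference blink suppression — in that order.
#'
#' @param rec an [EEGRecording-class].
#' @param pretrialMs pretrial baseline window (ms).
#' @param lowHz,highHz filter band edges (Hz).
#' @param spikeK spike-gate robust-z threshold.
#' @param padMs spike-gate padding (ms).
#' @param blinkSuppression apply the blink-suppression stage.
#' @return The cleaned recording.
#' @export
preprocessRecording <- function(rec, pretrialMs = 200, lowHz = 2, highHz = 43,
                                spikeK = 8, padMs = 200,
                                blinkSuppression = TRUE) {
  rec <- baselineCorrect(rec, pretrialMs)
  rec <- bandpassFir(rec, lowHz, highHz)
  rec <- gateSpikes(rec, spikeK, padMs)
  if (blinkSuppression) rec <- suppressBlinks(rec)
  rec
}

#' Preprocess every recording of a subject
#'
#' @param subject a [SubjectDataset-class].
#' @param ... passed to [preprocessRecording()].
#' @return The subject with all trials and the baseline cleaned.
#' @export
preprocessSubject <- function(subject, ...) {
  out <- subject
  out@trials <- lapply(subject@trials, preprocessRecording, ...)
  out@baseline <- preprocessRecording(subject@baseline, ...)
  out
}
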