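#' @include AllClasses.R
NULL

#' Frequency-band presets
#'
#' `bandsClassify3()` returns the three-band set used for classification
#' (Theta 4-7.5 Hz, Alpha 8-12 Hz, Beta 13-35 Hz); `bandsStandard5()` returns
#' the five-band decomposition (Delta 2-4, Theta 4-8, Alpha 8-12, Beta 12-30,
#' Gamma 30-40 Hz).  Band intervals are half-open `[low, high)` so shared
#' edges are never double-counted.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
bandsClassify3 <- function() {
  data.frame(name = c("Theta", "Alpha", "Beta"),
             low = c(4, 8, 13), high = c(7.5, 12, 35))
}

#' @rdname bandsClassify3
#' @export
bandsStandard5 <- function() {
  data.frame(name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
             low = c(2, 4, 8, 12, 30), high = c(4, 8, 12, 30, 40))
}

#' Default workload effect topography
#'
#' The 19 (channel, band) pairs whose oscillatory power increases with
#' workload level in the default synthetic cohort, spanning frontal, temporal,
#' parietal and occipital sites across the theta, alpha and beta bands, with
#' a common multiplicative power slope per workload level.
#'
#' @param slope multiplicative power increase per workload level (level 0 ->
#'   factor 1, level 2 -> factor `1 + 2 * slope`).
#' @return data.frame with columns `channel`, `band`, `slope`.
#' @export
defaultEffectMap <- function(slope = 0.15) {
  data.frame(
    channel = c("T7", "P7", "P7", "T8", "F8", "O1", "P8", "F4", "FC5", "F7",
                "FC5", "F4", "F7", "FC5", "P7", "F7", "T8", "T7", "T7"),
    band = c("Beta", "Alpha", "Theta", "Beta", "Beta", "Beta", "Beta",
             "Alpha", "Alpha", "Alpha", "Theta", "Theta", "Beta", "Beta",
             "Beta", "Theta", "Alpha", "Alpha", "Theta"),
    slope = slope
  )
}

.defaultHrParams <- function() {
  data.frame(condition = WORKLOAD_CONDITIONS,
             mean = c(72.47, 78.94, 73.76, 83.73),
             sd = c(8.9, 15.83, 9.9, 16.8))
}

.defaultAtwitParams <- function() {
  data.frame(condition = WORKLOAD_CONDITIONS,
             mean = c(4.4, 5.0, 4.7, 5.9),
             sd = c(2.2, 2.3, 2.7, 2.4))
}

#' Construct a CohortConfig
#'
#' All defaults encode the emulated experiment: 16 subjects, 14 channels at
#' 128 Hz, four conditions (Low/High communication delay crossed with
#' Low/High information dropout) mapped to ordinal workload levels 0, 1, 1, 2
#' so the two mixed conditions are exchangeable in expectation, two 4-minute
#' trials per condition, and a 1-minute resting baseline.  Heart-rate and
#' subjective-workload (1-7 scale) parameters default to the per-condition
#' means/standard deviations the pipeline is calibrated against.
#'
#' @param nSubjects number of subjects.
#' @param channelLabels montage names.
#' @param fs EEG sampling rate (Hz).
#' @param trialSeconds trial duration (s).
#' @param baselineSeconds baseline duration (s).
#' @param repetitions repetitions per condition.
#' @param conditions four ordered condition labels.
#' @param workloadLevels ordinal workload level per condition.
#' @param carrierBands bands synthesized as band-limited oscillations.
#' @param effectMap data.frame (channel, band, slope); see
#'   [defaultEffectMap()].
#' @param backgroundSd pink background amplitude (microvolt sd).
#' @param carrierSd per-band oscillation amplitude (microvolt sd).
#' @param subjectGainSd log-sd of per-(subject, channel) amplitude gain
#'   (cancels under baseline normalization).
#' @param trialGainSd log-sd of the per-trial broadband power gain (does not
#'   cancel; the dominant between-trial noise source).
#' @param slopeJitterSd log-sd of per-subject effect responsiveness.
#' @param hrParams per-condition heart-rate mean/sd (bpm).
#' @param hrTraitSd between-subject resting heart-rate sd (bpm).
#' @param hrResponseScale per-trial heart-rate condition-response sd,
#'   expressed as a fraction of the condition's reported std (the remaining
#'   variance is beat-to-beat noise that averages out within a trial).
#' @param hrResponseCap upper bound on the per-trial response sd (bpm), so
#'   the high-variability conditions keep most of their spread within trials
#'   and cohort means stay close to the calibration targets.
#' @param hrFs heart-rate sampling rate (Hz).
#' @param atwitParams per-condition subjective-workload mean/sd.
#' @param atwitTraitSd between-subject response-style sd.
#' @param seed cohort seed.
#' @return A validated [CohortConfig-class].
#' @export
cohortConfig <- function(nSubjects = 16, channelLabels = EMOTIV_MONTAGE,
                         fs = 128, trialSeconds = 240, baselineSeconds = 60,
                         repetitions = 2, conditions = WORKLOAD_CONDITIONS,
                         workloadLevels = c(0, 1, 1, 2),
                         carrierBands = bandsClassify3(),
                         effectMap = defaultEffectMap(),
                         backgroundSd = 10, carrierSd = 10,
                         subjectGainSd = 0.2, trialGainSd = 0.12,
                         slopeJitterSd = 0.25,
                         hrParams = .defaultHrParams(), hrTraitSd = 3.5,
                         hrResponseScale = 0.66, hrResponseCap = 8,
                         hrFs = 8,
                         atwitParams = .defaultAtwitParams(),
                         atwitTraitSd = 2.1, seed = 1L) {
  cfg <- new("CohortConfig", nSubjects = as.integer(nSubjects),
             channelLabels = channelLabels, fs = fs,
             trialSeconds = trialSeconds, baselineSeconds = baselineSeconds,
             repetitions = as.integer(repetitions), conditions = conditions,
             workloadLevels = workloadLevels, carrierBands = carrierBands,
             effectMap = effectMap, backgroundSd = backgroundSd,
             carrierSd = carrierSd, subjectGainSd = subjectGainSd,
             trialGainSd = trialGainSd, slopeJitterSd = slopeJitterSd,
             hrParams = hrParams, hrTraitSd = hrTraitSd,
             hrResponseScale = hrResponseScale,
             hrResponseCap = hrResponseCap, hrFs = hrFs,
             atwitParams = atwitParams, atwitTraitSd = atwitTraitSd,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# Band-limited Gaussian noise by spectral shaping: complex Gaussian spectrum
# restricted to [low, high) Hz, inverse FFT, unit expected variance.  No
# content is ever placed above fs/2, so the signal is alias-free by
# construction.
.synthBandNoise <- function(n, fs, low, high) {
  freqs <- (0:(n - 1)) * fs / n
  half <- seq_len(floor(n / 2) - 1) + 1L            # positive freqs, no DC
  sel <- half[freqs[half] >= low & freqs[half] < high]
  spec <- complex(length.out = n)
  if (length(sel)) {
    amp <- complex(real = stats::rnorm(length(sel)),
                   imaginary = stats::rnorm(length(sel)))
    spec[sel] <- amp
    spec[n + 2L - sel] <- Conj(amp)
    # Parseval: E[var(x)] = 4 * length(sel) / n^2 before scaling
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x * n / (2 * sqrt(length(sel)))
  } else {
    numeric(n)
  }
}

# Pink (1/f power) background over [0.5, fs/2 * 0.7] Hz with total sd `sd`.
.synthPink <- function(n, fs, sd) {
  freqs <- (0:(n - 1)) * fs / n
  half <- seq_len(floor(n / 2) - 1) + 1L
  lo <- 0.5
  hi <- 0.7 * fs / 2
  sel <- half[freqs[half] >= lo & freqs[half] < hi]
  spec <- complex(length.out = n)
  w <- 1 / sqrt(freqs[sel])                         # amplitude ~ 1/sqrt(f)
  amp <- complex(real = stats::rnorm(length(sel)) * w,
                 imaginary = stats::rnorm(length(sel)) * w)
  spec[sel] <- amp
  spec[n + 2L - sel] <- Conj(amp)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * sd * n / (2 * sqrt(sum(w^2)))
}

# Effect multiplier for one (channel, band) at a workload level.
.effectMultiplier <- function(effectMap, channel, band, level, slopeJitter) {
  hit <- effectMap$channel == channel & effectMap$band == band
  if (!any(hit)) return(1)
  1 + effectMap$slope[which(hit)[1]] * slopeJitter * level
}

.synthRecording <- function(config, subjectId, condition, repetition, level,
                            seconds, chGain, slopeJitter) {
  n <- round(seconds * config@fs)
  trialGain <- exp(stats::rnorm(1, 0, config@trialGainSd))   # power gain
  bands <- config@carrierBands
  dat <- matrix(0, length(config@channelLabels), n,
                dimnames = list(config@channelLabels, NULL))
  for (ci in seq_along(config@channelLabels)) {
    ch <- config@channelLabels[ci]
    x <- .synthPink(n, config@fs, config@backgroundSd)
    for (bi in seq_len(nrow(bands))) {
      mult <- .effectMultiplier(config@effectMap, ch, bands$name[bi],
                                level, slopeJitter)
      x <- x + .synthBandNoise(n, config@fs, bands$low[bi], bands$high[bi]) *
        config@carrierSd * sqrt(mult)
    }
    dat[ci, ] <- x * chGain[ci] * sqrt(trialGain)
  }
  EEGRecording(dat, config@fs, config@channelLabels, condition = condition,
               repetition = repetition, subjectId = subjectId)
}

#' Generate one synthetic subject
#'
#' EEG per trial is a pink (1/f) background plus band-limited Gaussian
#' oscillations whose power in each (channel, band) is scaled by the effect
#' map as a function of the condition's workload level; a per-channel subject
#' gain and a per-trial broadband gain add realistic between-recording
#' variability.  Heart rate and subjective workload are drawn from the
#' calibrated per-condition distributions with a shared subject trait.
#' Deterministic given `seed`.
#'
#' @param config a [CohortConfig-class].
#' @param subjectId subject identifier.
#' @param seed integer seed for this subject.
#' @return A [SubjectDataset-class] with `conditions x repetitions` trials
#'   and one baseline recording.
#' @export
generateSubject <- function(config, subjectId = "S1",
                            seed = config@seed) {
  validObject(config)
  withr::with_seed(as.integer(seed), {
    nCh <- length(config@channelLabels)
    chGain <- exp(stats::rnorm(nCh, 0, config@subjectGainSd))
    slopeJitter <- exp(stats::rnorm(1, 0, config@slopeJitterSd))
    hrTrait <- stats::rnorm(1, 0, config@hrTraitSd)
    atwitTrait <- stats::rnorm(1, 0, config@atwitTraitSd)

    trialInfo <- expand.grid(repetition = seq_len(config@repetitions),
                             condition = config@conditions,
                             stringsAsFactors = FALSE)
    trialInfo <- trialInfo[, c("condition", "repetition")]
    nHr <- round(config@trialSeconds * config@hrFs)

    trialsL <- vector("list", nrow(trialInfo))
    hrL <- vector("list", nrow(trialInfo))
    atwit <- integer(nrow(trialInfo))
    for (ti in seq_len(nrow(trialInfo))) {
      cond <- trialInfo$condition[ti]
      ci <- match(cond, config@conditions)
      level <- config@workloadLevels[ci]
      trialsL[[ti]] <- .synthRecording(config, subjectId, cond,
                                       trialInfo$repetition[ti], level,
                                       config@trialSeconds, chGain,
                                       slopeJitter)
      hp <- config@hrParams[ci, ]
      responseSd <- min(config@hrResponseScale * hp$sd, config@hrResponseCap)
      withinSd <- sqrt(max(hp$sd^2 - config@hrTraitSd^2 - responseSd^2, 1))
      hrMean <- hp$mean + hrTrait + stats::rnorm(1, 0, responseSd)
      hrL[[ti]] <- pmax(30, hrMean + stats::rnorm(nHr, 0, withinSd))
      ap <- config@atwitParams[ci, ]
      residSd <- sqrt(max(ap$sd^2 - config@atwitTraitSd^2, 0.25))
      atwit[ti] <- min(7L, max(1L, as.integer(round(
        stats::rnorm(1, ap$mean + atwitTrait, residSd)))))
    }
    baseline <- .synthRecording(config, subjectId, NA_character_,
                                NA_integer_, 0, config@baselineSeconds,
                                chGain, slopeJitter)
    new("SubjectDataset", subjectId = as.character(subjectId),
        trials = trialsL, baseline = baseline, hrSeries = hrL,
        atwitScores = atwit, trialInfo = trialInfo)
  })
}

# Subject seeds are split off the cohort seed by a fixed affine rule, kept
# inside the 32-bit integer range; the rule is recorded in the manifest.
.subjectSeed <- function(cohortSeed, index) {
  as.integer((as.numeric(cohortSeed) * 7919 + index * 104729) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' @param config a [CohortConfig-class]; `config@seed` seeds the cohort and
#'   per-subject seeds are derived from it.
#' @return A list of [SubjectDataset-class] of length `config@nSubjects`,
#'   with a `manifest` attribute (data.frame of subject ids, derived seeds
#'   and the seed-splitting rule).
#' @export
generateCohort <- function(config = cohortConfig()) {
  validObject(config)
  ids <- sprintf("S%02d", seq_len(config@nSubjects))
  seeds <- vapply(seq_len(config@nSubjects),
                  function(i) .subjectSeed(config@seed, i), integer(1))
  cohort <- mapply(function(id, s) generateSubject(config, id, s),
                   ids, seeds, SIMPLIFY = FALSE)
  attr(cohort, "manifest") <- data.frame(
    subject = ids, seed = seeds,
    rule = "seed_i = (cohort_seed * 7919 + i * 104729) mod 2147483647")
  cohort
}

#' Inject synthetic ocular and movement artifacts
#'
#' Adds low-frequency blink templates (raised-cosine bumps, frontally
#' weighted) at Poisson-distributed times and large-amplitude single-sample
#' spikes at random positions, recording the ground-truth locations in the
#' returned recording's `artifactTruth` so preprocessing can be asserted
#' against known events.
#'
#' @param rec an [EEGRecording-class].
#' @param blinkRate blink events per minute (>= 0).
#' @param spikeProb per-sample spike probability (>= 0), applied per channel.
#' @param blinkAmplitude peak blink amplitude at the frontal sites (uV).
#' @param spikeSdMultiple spike amplitude as a multiple of the channel sd.
#' @param seed integer seed.
#' @return The recording with artifacts added and ground truth recorded.
#' @export
injectArtifacts <- function(rec, blinkRate = 10, spikeProb = 1e-4,
                            blinkAmplitude = 150, spikeSdMultiple = 50,
                            seed = 1L) {
  stopifnot(blinkRate >= 0, spikeProb >= 0)
  if (blinkRate == 0 && spikeProb == 0) return(rec)
  withr::with_seed(as.integer(seed), {
    dat <- rec@data
    fs <- rec@fs
    n <- ncol(dat)
    labels <- rec@channelLabels
    frontalW <- ifelse(labels %in% c("AF3", "AF4", "F7", "F8"), 1,
                       ifelse(labels %in% c("F3", "F4", "FC5", "FC6"),
                              0.4, 0.1))
    blinkSamples <- integer(0)
    if (blinkRate > 0) {
      nBlinks <- stats::rpois(1, blinkRate * n / fs / 60)
      len <- round(0.4 * fs)                       # 400 ms blink template
      template <- blinkAmplitude * sin(pi * seq_len(len) / len)^2
      if (nBlinks > 0) {
        blinkSamples <- sort(sample.int(n - len, nBlinks))
        for (s in blinkSamples) {
          idx <- s:(s + len - 1L)
          dat[, idx] <- dat[, idx] +
            outer(frontalW, template)
        }
      }
    }
    spikes <- data.frame(channel = character(0), sample = integer(0))
    if (spikeProb > 0) {
      for (ci in seq_len(nrow(dat))) {
        pos <- which(stats::runif(n) < spikeProb)
        if (length(pos)) {
          amp <- spikeSdMultiple * stats::sd(dat[ci, ]) *
            sample(c(-1, 1), length(pos), replace = TRUE)
          dat[ci, pos] <- dat[ci, pos] + amp
          spikes <- rbind(spikes, data.frame(channel = labels[ci],
                                             sample = pos))
        }
      }
    }
    out <- rec
    out@data <- dat
    out@artifactTruth <- list(blinkSamples = blinkSamples,
                              blinkLengthSamples = round(0.4 * fs),
                              spikes = spikes)
    out
  })
}
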