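test_that("a generated subject has the experiment's structure", {
  cfg <- cohortConfig(trialSeconds = 240, seed = 5)
  sub <- generateSubject(cfg, "S01", seed = 11)
  expect_length(trials(sub), 8)                       # 4 conditions x 2 reps
  rec <- trials(sub)[[1]]
  expect_equal(dim(eegData(rec)), c(14, 30720))       # 240 s x 128 Hz
  expect_equal(samplingRate(rec), 128)
  expect_equal(channelLabels(rec), cfg@channelLabels)
  expect_equal(dim(eegData(baselineRecording(sub))), c(14, 60 * 128))
  expect_length(heartRate(sub)[[1]], 240 * 8)         # 8 Hz heart rate
  expect_true(all(atwitScores(sub) >= 1 & atwitScores(sub) <= 7))
})

test_that("generation is bitwise deterministic under a fixed seed", {
  cfg <- smallConfig(trialSeconds = 10, baselineSeconds = 5)
  a <- generateSubject(cfg, "S01", seed = 99)
  b <- generateSubject(cfg, "S01", seed = 99)
  expect_identical(eegData(trials(a)[[3]]), eegData(trials(b)[[3]]))
  expect_identical(heartRate(a), heartRate(b))
  expect_identical(atwitScores(a), atwitScores(b))
  c <- generateSubject(cfg, "S01", seed = 100)
  expect_false(identical(eegData(trials(a)[[1]]), eegData(trials(c)[[1]])))
})

test_that("a positive beta effect slope raises beta power under high load", {
  # strong construction-level effect at T7 only; Monte-Carlo over subjects
  em <- data.frame(channel = "T7", band = "Beta", slope = 0.5)
  cfg <- smallConfig(trialSeconds = 20, baselineSeconds = 5, effectMap = em)
  hits <- vapply(1:60, function(s) {
    sub <- generateSubject(cfg, "S", seed = 1000 + s)
    pow <- vapply(trials(sub), function(rec) {
      psd <- windowedPsd(rec, windowSeconds = 10, overlap = 0.5)
      mean(bandPower(psd, 13, 35)[, "T7"])
    }, numeric(1))
    cond <- sub@trialInfo$condition
    mean(pow[cond == "HighHigh"]) > mean(pow[cond == "LowLow"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort generation yields distinct seeded subjects plus manifest", {
  cfg <- smallConfig(nSubjects = 3, trialSeconds = 10, baselineSeconds = 5)
  coh <- generateCohort(cfg)
  expect_length(coh, 3)
  man <- attr(coh, "manifest")
  expect_equal(man$subject, c("S01", "S02", "S03"))
  expect_equal(anyDuplicated(man$seed), 0L)
  expect_false(identical(eegData(trials(coh[[1]])[[1]]),
                         eegData(trials(coh[[2]])[[1]])))
  one <- generateCohort(smallConfig(nSubjects = 1, trialSeconds = 10,
                                    baselineSeconds = 5))
  expect_length(one, 1)
})

test_that("cohort heart-rate means track the calibrated per-condition targets", {
  targets <- c(72.47, 78.94, 73.76, 83.73)
  devs <- t(vapply(1:9, function(s) {
    cfg <- cohortConfig(nSubjects = 16, trialSeconds = 10,
                        baselineSeconds = 5, seed = 300 + s)
    coh <- generateCohort(cfg)
    abs(conditionSummary(hrMeasures(coh))$mean - targets)
  }, numeric(4)))
  # per condition, the cohort mean lands within 2 bpm in a majority of seeds
  expect_true(all(colSums(devs < 2) >= 5))
})

test_that("subjective workload means reproduce the condition ordering", {
  agree <- vapply(1:9, function(s) {
    cfg <- cohortConfig(nSubjects = 16, trialSeconds = 10,
                        baselineSeconds = 5, seed = 500 + s)
    m <- conditionSummary(atwitMeasures(generateCohort(cfg)))$mean
    m[4] == max(m) && m[1] == min(m)
  }, logical(1))
  expect_gte(mean(agree), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(conditions = c("A", "B")), "4 entries")
  expect_error(cohortConfig(fs = 40), "twice the highest")
  expect_error(cohortConfig(
    atwitParams = data.frame(condition = eegworkload:::WORKLOAD_CONDITIONS,
                             mean = 4, sd = -1)), "standard deviations")
  expect_error(cohortConfig(
    effectMap = data.frame(channel = "XX", band = "Beta", slope = 1)),
    "channels")
})

test_that("artifact injection is a seeded no-op-able overlay with truth", {
  rec <- sineRecording(c(10, 10, 10, 10), seconds = 30, fs = 128,
                       labels = c("AF3", "AF4", "F7", "O2"))
  expect_identical(injectArtifacts(rec, blinkRate = 0, spikeProb = 0), rec)
  a <- injectArtifacts(rec, blinkRate = 12, spikeProb = 2e-4, seed = 4)
  b <- injectArtifacts(rec, blinkRate = 12, spikeProb = 2e-4, seed = 4)
  expect_identical(eegData(a), eegData(b))
  expect_identical(a@artifactTruth, b@artifactTruth)

  # 50x-sd spikes exceed an 8x robust-sd threshold at every injected location
  sp <- injectArtifacts(rec, blinkRate = 0, spikeProb = 5e-4,
                        spikeSdMultiple = 50, seed = 9)
  truth <- sp@artifactTruth$spikes
  expect_gt(nrow(truth), 0)
  for (i in seq_len(nrow(truth))) {
    ch <- match(truth$channel[i], channelLabels(sp))
    x <- eegData(sp)[ch, ]
    z <- abs(x - median(x)) / mad(x)
    expect_gt(z[truth$sample[i]], 8)
  }
})

test_that("synthesized spectra contain no content above Nyquist band edges", {
  cfg <- smallConfig(trialSeconds = 10, baselineSeconds = 5)
  rec <- trials(generateSubject(cfg, "S", 3))[[1]]
  x <- eegData(rec)[1, ]
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * samplingRate(rec) / length(x)
  hi <- freqs > 45 & freqs < samplingRate(rec) / 2
  expect_lt(sum(spec[hi]), 1e-12 * sum(spec))
})
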