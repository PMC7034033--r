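protoFast <- function(nRepeats = 10, cvFolds = 3, seed = 1)
  evalProtocol(nRepeats = nRepeats, cvFolds = cvFolds, seed = seed)

# windows x features table with class-dependent Gaussian features
gaussTable <- function(n = 200, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c("LowLow", "LowHigh", "HighLow", "HighHigh"), length.out = n)
  v <- matrix(rnorm(n * p), n)
  v[, 1] <- v[, 1] + sep * as.numeric(factor(y, levels = unique(y)))
  toyTable(v, y)
}

test_that("LDA separates well-separated classes nearly perfectly", {
  tab <- gaussTable(sep = 6, seed = 2)
  ev <- ldaEval(tab, protocol = protoFast())
  expect_gte(ev$meanAcc, 99)
  expect_gte(ev$cvMeanAcc, 99)
})

test_that("label-permuted data stay at the 25% chance level", {
  set.seed(3)
  tab <- gaussTable(n = 400, sep = 3, seed = 3)
  perm <- toyTable(t(SummarizedExperiment::assay(tab, "values")),
                   sample(conditionLabels(tab)))
  ev <- ldaEval(perm, protocol = protoFast(nRepeats = 20))
  nTest <- round(0.3 * 400)
  se <- 100 * sqrt(0.25 * 0.75 / nTest) / sqrt(20)
  expect_lt(abs(ev$meanAcc - 25), 3 * 100 * sqrt(0.25 * 0.75 / nTest))
})

test_that("evaluation is deterministic given the protocol seed", {
  tab <- gaussTable(sep = 1, seed = 4)
  a <- ldaEval(tab, protocol = protoFast(seed = 7))
  b <- ldaEval(tab, protocol = protoFast(seed = 7))
  expect_identical(a, b)
  c <- ldaEval(tab, protocol = protoFast(seed = 8))
  expect_false(identical(a$perRepeat, c$perRepeat))
})

test_that("feature order within a prefix set does not change accuracy", {
  tab <- gaussTable(sep = 2, seed = 5)
  f <- featureIds(tab)
  a <- ldaEval(tab, f[1:3], protoFast())
  b <- ldaEval(tab, f[3:1], protoFast())
  expect_equal(a$meanAcc, b$meanAcc)
})

test_that("class starvation is reported with the class name", {
  y <- c(rep("LowLow", 40), rep("LowHigh", 40), rep("HighLow", 40),
         rep("HighHigh", 1))
  tab <- toyTable(matrix(rnorm(121 * 2), 121), y)
  expect_error(ldaEval(tab, protocol = protoFast()), "HighHigh")
})

test_that("accuracy curves follow the ranking prefixes and plateau", {
  tab <- gaussTable(n = 240, sep = 3, seed = 6)
  ids <- featureIds(tab)                     # feature 1 is informative
  cu <- accuracyCurve(tab, ids, protoFast())
  expect_s4_class(cu, "AccuracyCurve")
  expect_equal(featureCounts(cu), 1:4)
  # informative first feature beats a pure-noise singleton clearly
  noiseFirst <- ldaEval(tab, ids[2], protoFast())
  expect_gt(meanAccuracy(cu)[1], noiseFirst$meanAcc + 10)
  # adding noise features after saturation stays within the noise band
  expect_lt(abs(meanAccuracy(cu)[4] - meanAccuracy(cu)[1]), 10)
  one <- accuracyCurve(tab, ids[1], protoFast())
  expect_length(meanAccuracy(one), 1)
})

test_that("the stopping criterion applies the three-in-a-row rule", {
  mkCurve <- function(means, sds = rep(0.5, length(means)), n = 30) {
    set.seed(1)
    per <- vector("list", length(means))
    for (i in seq_along(means)) {
      # equal consecutive means are represented by identical score sets,
      # so the corresponding t-tests are exactly non-significant
      per[[i]] <- if (i > 1 && means[i] == means[i - 1]) per[[i - 1]]
                  else pmin(100, pmax(0, rnorm(n, means[i], sds[i])))
    }
    new("AccuracyCurve", featureCounts = seq_along(means),
        meanAcc = vapply(per, mean, numeric(1)),
        sdAcc = vapply(per, sd, numeric(1)), perRepeat = per,
        cvMeanAcc = rep(NA_real_, length(means)))
  }
  # significant rises for counts 1..4, flat from 4 on: S S S N N N -> 4
  cu <- mkCurve(c(40, 50, 60, 70, 70, 70, 70))
  expect_equal(as.integer(stoppingCriterion(cu, evalProtocol())), 4L)
  # flat from the start -> 1
  flat <- mkCurve(rep(50, 5))
  expect_equal(as.integer(stoppingCriterion(flat, evalProtocol())), 1L)
  # monotone significant growth -> max count with a no-plateau warning
  rise <- mkCurve(seq(30, 90, by = 10))
  expect_warning(sel <- stoppingCriterion(rise, evalProtocol()),
                 "no plateau")
  expect_equal(as.integer(sel), 7L)
  expect_error(stoppingCriterion(mkCurve(c(40, 50)), evalProtocol()),
               "at least")
})

test_that("reference accuracies cover the six indicators", {
  cfg <- smallConfig(trialSeconds = 30, baselineSeconds = 20,
                     effectMap = data.frame(channel = c("T7", "P8"),
                                            band = "Beta", slope = 0.8))
  tab <- subjectFeatureTable(generateSubject(cfg, "S01", 31),
                             includeRatios = TRUE)
  ref <- referenceAccuracies(tab, protoFast(nRepeats = 5))
  expect_equal(nrow(ref), 6)
  expect_setequal(ref$indicator, c("Theta", "Alpha", "Beta",
                                   "EI", "TLI", "TBR"))
  # with beta-only effects the beta indicator outranks theta and alpha
  acc <- setNames(ref$mean_acc_pct, ref$indicator)
  expect_gt(acc["Beta"], acc["Theta"])
  expect_gt(acc["Beta"], acc["Alpha"])
})

test_that("grand averaging across subjects is reproducible and aligned", {
  t1 <- gaussTable(sep = 2, seed = 8)
  t2 <- gaussTable(sep = 2, seed = 9)
  ids <- featureIds(t1)[1:2]
  c1 <- accuracyCurve(t1, ids, protoFast())
  c2 <- accuracyCurve(t2, ids, protoFast())
  g <- grandAverageCurve(list(c1, c2))
  expect_equal(meanAccuracy(g),
               (meanAccuracy(c1) + meanAccuracy(c2)) / 2)
  expect_identical(meanAccuracy(grandAverageCurve(list(c1, c2))),
                   meanAccuracy(grandAverageCurve(list(c1, c2))))
})
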