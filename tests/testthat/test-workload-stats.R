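rm4 <- function(m, metric = "metric")
  repeatedMeasures(m, metric, eegworkload:::WORKLOAD_CONDITIONS[1:ncol(m)])

test_that("the normality gate passes normal data and flags lognormal", {
  pass <- vapply(1:40, function(s) {
    set.seed(s)
    g <- suppressWarnings(normalityGate(rm4(matrix(rnorm(64), 16, 4))))
    !g$transformed
  }, logical(1))
  expect_gte(mean(pass), 0.85)

  # heavy-tailed data: rejected raw, restored by the log transform
  set.seed(99)
  m <- matrix(exp(rnorm(64, 0, 1.5)), 16, 4)
  g <- normalityGate(rm4(m))
  expect_true(g$transformed)
  expect_lt(g$pRaw, 0.05)
  expect_gt(g$pLog, 0.05)
  expect_true(g$useNonparametric)

  expect_error(normalityGate(rm4(matrix(5, 8, 4))), "constant")
})

test_that("Friedman test: identity, perfect concordance, oracle", {
  # identical columns -> fully tied ranks -> chi2 0, p 1
  same <- rm4(matrix(rep(rnorm(16), 4), 16, 4))
  fr <- friedmanTest(same)
  expect_equal(fr$chi2, 0)
  expect_equal(fr$p, 1)

  # every subject ranks the conditions identically: chi2 = n(k-1) = 48
  conc <- rm4(matrix(rep(1:4, each = 16), 16, 4) + rnorm(64, 0, 0.01))
  expect_equal(friedmanTest(conc)$chi2, 48, tolerance = 1e-9)

  # random matrices match the step-by-step oracle and stats::friedman.test
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rnorm(32), 8, 4)
    fr <- friedmanTest(rm4(m))
    expect_equal(fr$chi2, oracleFriedman(m), tolerance = 1e-9)
    ref <- stats::friedman.test(m)
    expect_equal(fr$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(fr$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(friedmanTest(rm4(matrix(1:2, 2, 1))), "at least 2")
})

test_that("Wilcoxon post-hoc: Bonferroni threshold and hand oracle", {
  set.seed(21)
  m <- matrix(rnorm(64), 16, 4)
  ph <- wilcoxonPosthoc(rm4(m), familyAlpha = 0.05)
  expect_equal(round(ph$bonferroniAlpha, 4), 0.0083)
  expect_equal(nrow(ph$posthoc), 6)

  # identical paired columns -> warned, p = 1, nothing significant
  same <- rm4(cbind(m[, 1], m[, 1], m[, 3], m[, 4]))
  expect_warning(ph2 <- wilcoxonPosthoc(same), "all-zero")
  expect_equal(ph2$posthoc$p[1], 1)
  expect_false(ph2$posthoc$significant[1])

  # statistic cross-check: asymptotic p from the hand-computed V
  a <- c(3.1, 4.5, 2.2, 6.6, 5.1, 7.3, 1.2, 4.4)
  b <- c(2.5, 4.9, 1.1, 5.0, 5.1, 6.0, 2.0, 3.9)
  V <- oracleSignedRankV(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(unname(ref$statistic), V)
  ph3 <- wilcoxonPosthoc(rm4(cbind(a, b, a + 10, b - 10)))
  expect_equal(ph3$posthoc$p[1], ref$p.value, tolerance = 1e-12)
})

test_that("Friedman type-I error is calibrated under exchangeable nulls", {
  set.seed(1234)
  rejections <- vapply(1:1000, function(i) {
    friedmanTest(rm4(matrix(rnorm(64), 16, 4)))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("Friedman is invariant to monotone transforms of subject rows", {
  set.seed(31)
  m <- matrix(abs(rnorm(32)) + 0.1, 8, 4)
  a <- friedmanTest(rm4(m))$chi2
  b <- friedmanTest(rm4(exp(m)))$chi2
  m2 <- m
  for (i in 1:8) m2[i, ] <- m[i, ]^(i %% 3 + 1)     # per-row monotone map
  expect_equal(a, b)
  expect_equal(a, friedmanTest(rm4(m2))$chi2)
})

test_that("EEG aggregation reduces to means with the right invariances", {
  set.seed(41)
  y <- rep(eegworkload:::WORKLOAD_CONDITIONS, each = 3)
  v <- matrix(exp(rnorm(24)), 12, 2)
  tabs <- lapply(c("S1", "S2"), function(s) toyTable(v, y, subjectId = s))
  # single feature / single condition windows: cell = mean of those values
  rmOne <- aggregateEegMetric(tabs, "BetaC1")
  expect_equal(measuresMatrix(rmOne)["S1", "LowLow"], mean(v[1:3, 1]))

  # window permutation invariance
  perm <- sample(12)
  tabsP <- lapply(c("S1", "S2"), function(s)
    toyTable(v[perm, , drop = FALSE], y[perm], subjectId = s))
  expect_equal(measuresMatrix(aggregateEegMetric(tabsP, c("BetaC1",
                                                          "BetaC2"))),
               measuresMatrix(aggregateEegMetric(tabs, c("BetaC1",
                                                         "BetaC2"))))
  expect_error(aggregateEegMetric(tabs, character(0)), "non-empty")
})

test_that("injected workload effects surface in the aggregated EEG metric", {
  hits <- vapply(1:5, function(s) {
    cfg <- smallConfig(nSubjects = 4, trialSeconds = 30,
                       baselineSeconds = 20, seed = 700 + s)
    coh <- generateCohort(cfg)
    tabs <- lapply(coh, subjectFeatureTable)
    em <- defaultEffectMap()
    rmE <- aggregateEegMetric(tabs, paste0(em$band, em$channel))
    m <- colMeans(measuresMatrix(rmE))
    m["HighHigh"] > m["LowLow"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("validateMetric assembles a complete report", {
  set.seed(51)
  m <- matrix(rnorm(64, mean = rep(c(0, 0.2, 0.2, 1.5), each = 16)), 16, 4)
  rep <- validateMetric(rm4(m, "ATWIT"))
  expect_s4_class(rep, "ValidationReport")
  expect_equal(rep@bonferroniAlpha, 0.05 / 6)
  expect_equal(nrow(rep@posthoc), 6)
  expect_true(rep@useNonparametric)
  expect_output(show(rep), "Friedman")
})
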