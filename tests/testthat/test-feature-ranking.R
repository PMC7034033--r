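test_that("equal-frequency discretization balances bin populations", {
  expect_equal(as.numeric(table(discretizeFeature(1:10, 5))), rep(2, 5))
  expect_warning(d <- discretizeFeature(rep(3, 10)), "constant")
  expect_equal(d, rep(1L, 10))
  set.seed(2)
  d2 <- discretizeFeature(rnorm(1000), 5)
  expect_equal(as.numeric(table(d2)), rep(200, 5))
  # populations differ by at most 1 when n is not a multiple of bins
  d3 <- discretizeFeature(rnorm(103), 5)
  expect_lte(diff(range(table(d3))), 1)
})

test_that("mutual information matches analytic values and the oracle", {
  # exact independence: uniform 2x2 joint laid out explicitly
  x <- rep(c(1, 1, 2, 2), 25)
  y <- rep(c(1, 2, 1, 2), 25)
  expect_equal(mutualInformation(x, y), 0)
  # Y = X over 4 equiprobable values -> log2(4) = 2 bits
  x4 <- rep(1:4, each = 10)
  expect_equal(mutualInformation(x4, x4), 2)
  # arbitrary joint tables against the brute-force oracle
  set.seed(11)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(mutualInformation(a, b), oracleMI(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mutualInformation(1:4, 1:5), "equal length")
})

test_that("JMI puts a label-copy feature first and penalizes duplicates", {
  set.seed(3)
  y <- rep(c("LowLow", "LowHigh", "HighLow", "HighHigh"), each = 15)
  copy <- as.numeric(factor(y)) + rnorm(60, 0, 0.01)
  noise <- matrix(rnorm(60 * 3), 60)
  tab <- toyTable(cbind(A = copy, N1 = noise[, 1], N2 = noise[, 2],
                        N3 = noise[, 3]), y)
  rk <- jmiRank(tab, nBins = 4)
  expect_equal(rankedFeatures(rk)[1], "A")            # the copy feature

  # duplicate of the top feature vs a complementary feature (XOR-style):
  # y depends on parity of (a, b); a alone is informative, its duplicate
  # adds nothing, b is complementary.
  set.seed(4)
  a <- sample(0:1, 200, replace = TRUE)
  b <- sample(0:1, 200, replace = TRUE)
  yx <- ifelse(xor(a, b), "HighHigh", "LowLow")
  yx[sample(200, 30)] <- "LowHigh"                    # symmetry breaker
  tab2 <- toyTable(cbind(Fa = a + rnorm(200, 0, 0.01),
                         FaDup = a + rnorm(200, 0, 0.01),
                         Fb = b + rnorm(200, 0, 0.01)), yx)
  rk2 <- jmiRank(tab2, nBins = 2)
  ord <- rankedFeatures(rk2)
  expect_lt(match("Fb", ord), max(match(c("Fa", "FaDup"), ord)))
})

test_that("JMI agrees with brute-force criterion evaluation at every step", {
  set.seed(9)
  for (rep in 1:3) {
    y <- sample(rep(c("LowLow", "LowHigh", "HighLow", "HighHigh"), 15))
    v <- matrix(rnorm(60 * 4), 60)
    v[, 1] <- v[, 1] + as.numeric(factor(y))
    v[, 3] <- v[, 3] + 0.5 * as.numeric(factor(y))
    tab <- toyTable(v, y)
    nBins <- 3
    rk <- jmiRank(tab, nBins = nBins)
    d <- apply(v, 2, function(col) {
      r <- rank(col, ties.method = "first")
      floor((r - 1) * nBins / length(col)) + 1
    })
    colnames(d) <- paste0("BetaC", 1:4)
    d <- d[, order(colnames(d))]
    expect_equal(rankedFeatures(rk),
                 oracleJMI(d, as.integer(factor(y)), nBins))
  }
})

test_that("information gain ranking equals per-feature MI, descending", {
  set.seed(5)
  y <- rep(c("LowLow", "LowHigh", "HighLow", "HighHigh"), each = 20)
  v <- matrix(rnorm(80 * 5), 80)
  v[, 2] <- v[, 2] + as.numeric(factor(y))
  tab <- toyTable(v, y)
  rk <- infoGainRank(tab, nBins = 5)
  expect_equal(rankedFeatures(rk)[1], "BetaC2")
  # scores agree with mutualInformation applied feature by feature
  for (i in seq_along(rankedFeatures(rk))) {
    f <- rankedFeatures(rk)[i]
    col <- SummarizedExperiment::assay(tab, "values")[f, ]
    expect_equal(rankingScores(rk)[i],
                 mutualInformation(discretizeFeature(col, 5),
                                   as.integer(factor(y))),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(rankingScores(rk)) <= 1e-12))

  # JMI's first pick coincides with InfoGain's top feature
  expect_equal(rankedFeatures(jmiRank(tab, 5))[1], rankedFeatures(rk)[1])
})

test_that("t-statistic ranking matches the textbook two-sample formula", {
  y <- rep(c("LowLow", "HighHigh"), each = 3)
  v <- matrix(c(1, 2, 3, 7, 8, 9,          # strong shift
                5, 5.1, 4.9, 5, 5.1, 4.9), # none
              6, 2)
  tab <- toyTable(v, y)
  rk <- tTestRank(tab)
  expect_equal(rankedFeatures(rk)[1], "BetaC1")
  tt <- t.test(v[4:6, 1], v[1:3, 1], var.equal = TRUE)
  expect_equal(rankingScores(rk)[1], abs(unname(tt$statistic)),
               tolerance = 1e-12)
  expect_lt(rankingScores(rk)[2], 0.5)

  y4 <- rep(c("LowLow", "LowHigh", "HighLow", "HighHigh"), each = 1)
  expect_error(tTestRank(toyTable(matrix(rnorm(8), 4, 2), y4)),
               "at least 2 windows")
})

test_that("rankings are complete permutations and bit-reproducible", {
  cfg <- smallConfig(trialSeconds = 30, baselineSeconds = 20)
  tab <- subjectFeatureTable(generateSubject(cfg, "S01", 13))
  for (rk in list(jmiRank(tab), infoGainRank(tab), tTestRank(tab))) {
    expect_setequal(rankedFeatures(rk), featureIds(tab))
    expect_length(rankedFeatures(rk), 42)
  }
  expect_identical(rankedFeatures(jmiRank(tab)), rankedFeatures(jmiRank(tab)))
})

test_that("the correlation screen flags collinear ratios, keeps novel ones", {
  set.seed(8)
  n <- 120
  theta <- exp(rnorm(n, 0, 0.5))
  beta <- exp(rnorm(n, 0, 0.05))          # stable beta: TBR ~ theta
  alpha <- exp(rnorm(n, 0, 0.5))
  dummy <- rnorm(n)                        # unrelated injected feature
  y <- rep(c("LowLow", "HighHigh"), n / 2)
  vals <- cbind(theta, alpha, beta, theta / beta, dummy)
  tab <- FeatureTable(t(vals), channel = rep("T7", 5),
                      band = c("Theta", "Alpha", "Beta", "TBR", "Dummy"),
                      type = c("power", "power", "power", "ratio", "ratio"),
                      condition = y)
  rownames(tab) <- c("ThetaT7", "AlphaT7", "BetaT7", "TBRT7", "DummyT7")
  scr <- correlationScreen(tab)
  expect_true("TBRT7" %in% scr$excluded$feature)
  expect_false("DummyT7" %in% scr$excluded$feature)
  expect_equal(unname(diag(scr$correlations)), rep(1, 5))
  expect_equal(nrow(scr$screened), 3)
})
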