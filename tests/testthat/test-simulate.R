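test_that("generating basis functions take their closed-form values", {
  b <- oscillationBases(c(0, 0.25, 1))
  expect_equal(unname(b[, 1]), c(1, 0, 1))
  expect_equal(unname(b["phi1", 2]), 0, tolerance = 1e-12)  # cos(pi/2) = 0
  expect_equal(unname(b["phi3", 3]), exp(-2))
  expect_equal(unname(b["phi2", 3]), exp(-0.5) * sin(2 * pi),
               tolerance = 1e-12)
})

test_that("TDEG mean curves follow the exponential score model", {
  cfg <- trajSimConfig(nGenes = 10, nTdeg = 5, nCells = 4)
  t <- c(0, 0.3, 0.6, 1)
  set.seed(1)
  td <- tdegMeanCurves(cfg, t)
  phi <- oscillationBases(t)
  manual <- exp((td$xi * rep(c(1, 0.5, 0.25), each = 5)) %*% phi)
  expect_equal(td$mu, manual)
  # xi = 0 gives a flat unit mean; xi = (1,0,0) gives e at t = 0
  xi0 <- matrix(c(0, 0, 0), 1)
  expect_equal(drop(exp((xi0 * c(1, 0.5, 0.25)) %*% phi)), rep(1, 4))
  xi1 <- matrix(c(1, 0, 0), 1)
  expect_equal(drop(exp((xi1 %*% (c(1, 0.5, 0.25) * phi))))[1], exp(1))
})

test_that("log-mean variance at t = 0 matches the linear-combination formula", {
  cfg <- trajSimConfig(nGenes = 10001, nTdeg = 10000, nCells = 2)
  set.seed(83)
  td <- tdegMeanCurves(cfg, c(0, 1))
  v <- var(log(td$mu[, 1]))
  expect_equal(v, 1^2 + 0.25^2, tolerance = 0.05)   # phi2(0) = 0
})

test_that("null genes get constant uniform levels below the TDEG median", {
  cfg <- trajSimConfig(nGenes = 5000, nTdeg = 500, nCells = 20)
  set.seed(89)
  td <- tdegMeanCurves(cfg, seq(0, 1, length.out = 20))
  cNull <- nontdegMeans(cfg, td$mu)
  m <- median(td$mu)
  expect_length(cNull, 4500)
  expect_true(all(cNull >= 0 & cNull <= m))
  expect_equal(mean(cNull), m / 2, tolerance = 0.03)
  sim <- simulateTrajectoryData(trajSimConfig(
    nGenes = 50, nTdeg = 10, nCells = 30, seed = 1))
  mu <- SummarizedExperiment::assay(sim, "mu")
  expect_true(all(apply(mu[11:50, ], 1, function(r) max(r) == min(r))))
  expect_true(all(apply(mu[1:10, ], 1, function(r) max(r) > min(r))))
})

test_that("ZINB thinning has the advertised mean and zero probability", {
  cfg <- trajSimConfig()
  set.seed(97)
  draws <- zinbCounts(rep(2, 1e5), cfg)
  se <- sqrt(var(draws) / 1e5)
  expect_lt(abs(mean(draws) - 0.25 * 2), 3 * se)
  # P(W = 0) = 0.75 + 0.25 / (1 + mu) at theta = 1
  expect_lt(abs(mean(draws == 0) - (0.75 + 0.25 / 3)),
            3 * sqrt(0.83 * 0.17 / 1e5) + 0.005)
  expect_error(zinbCounts(c(-1, 2), cfg), "nonnegative")
})

test_that("dataset-level zero fraction matches the closed-form mixture", {
  sim <- simulateTrajectoryData(trajSimConfig(
    nGenes = 800, nTdeg = 100, nCells = 200, seed = 101))
  counts <- simCounts(sim)
  mu <- as.matrix(SummarizedExperiment::assay(sim, "mu"))
  expected <- mean(0.75 + 0.25 / (1 + mu))
  expect_equal(mean(counts == 0), expected, tolerance = 0.01)
  expect_gt(mean(counts == 0), 0.75)                 # dropout floor
})

test_that("simulated datasets are reproducible and honor the config", {
  cfg <- trajSimConfig(nGenes = 120, nTdeg = 30, nCells = 50, seed = 7)
  s1 <- simulateTrajectoryData(cfg)
  s2 <- simulateTrajectoryData(cfg)
  expect_identical(simCounts(s1), simCounts(s2))
  expect_equal(dim(s1), c(120L, 50L))
  expect_equal(sum(simTruth(s1)), 30L)
  expect_equal(range(simPseudotime(s1)), c(0, 1))
  expect_equal(diff(simPseudotime(s1)), rep(1 / 49, 49))
  # degenerate all-null config for type-I-error studies
  s0 <- simulateTrajectoryData(trajSimConfig(
    nGenes = 40, nTdeg = 0, nCells = 30, seed = 5))
  expect_equal(sum(simTruth(s0)), 0L)
  expect_error(trajSimConfig(nGenes = 10, nTdeg = 20), "exceed")
  expect_error(trajSimConfig(dropoutKeepProb = 0), "dropoutKeepProb")
  expect_equal(trajSimConfig(preset = "moderate-zi")$dropoutKeepProb, 0.5)
})

test_that("log TDEG means form the designed Gaussian process on the diagonal", {
  cfg <- trajSimConfig(nGenes = 4001, nTdeg = 4000, nCells = 5)
  t5 <- seq(0, 1, length.out = 5)
  set.seed(103)
  td <- tdegMeanCurves(cfg, t5)
  phi <- oscillationBases(t5)
  target <- colSums(c(1, 0.5, 0.25)^2 * phi^2)
  observed <- apply(log(td$mu), 2, var)
  expect_equal(unname(observed), unname(target), tolerance = 0.08)
})
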