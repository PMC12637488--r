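test_that("an all-constant dataset yields no discoveries", {
  counts <- matrix(5, 20, 30,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  t <- seq_len(30)
  res <- suppressWarnings(
    runTrajFpcTest(counts, t, permutations = 10, seed = 1))
  tab <- resultTable(res)
  expect_equal(tab$p, rep(1, 20))
  expect_equal(sum(tab$is_tdeg), 0)
  expect_true(all(tab$constant))
})

test_that("a single strong signal gene attains the minimum p-value", {
  set.seed(53)
  n <- 80; G <- 60
  t <- seq(0, 1, length.out = n)
  basis <- fpcBasis()
  E <- orthoOscillationCoefs(basis)
  curves <- matrix(rnorm(G * n, sd = 0.3), G, n)
  strong <- 10 * drop(evalBasis(basis, t) %*% E[, 1])
  curves[7, ] <- curves[7, ] + strong
  res <- runTrajFpcTest(exp(curves), t, scale = "counts",
                        permutations = 50, seed = 54)
  tab <- resultTable(res)
  expect_equal(which.min(tab$p), 7L)
  expect_equal(which.max(tab$D), 7L)
})

test_that("identical inputs and seed give bit-identical results", {
  sim <- smallSim()
  r1 <- runTrajFpcTest(sim, permutations = 25, seed = 99)
  r2 <- runTrajFpcTest(sim, permutations = 25, seed = 99)
  expect_identical(resultTable(r1), resultTable(r2))
})

test_that("within one run a larger D never receives a larger p", {
  sim <- smallSim()
  tab <- resultTable(runTrajFpcTest(sim, permutations = 30, seed = 61))
  o <- order(tab$D, decreasing = TRUE)
  expect_true(all(diff(tab$p[o]) >= 0))
  expect_true(all(tab$q >= 0 & tab$q <= 1))
})

test_that("TIG refinement is nearly idempotent on clean signal", {
  set.seed(67)
  n <- 100; nSignal <- 50; nNull <- 150
  t <- seq(0, 1, length.out = n)
  basis <- fpcBasis()
  E <- orthoOscillationCoefs(basis)
  Z <- sweep(matrix(rnorm(nSignal * 3), nSignal, 3), 2,
             sqrt(c(1, 0.5, 0.25)), "*")
  signal <- (Z %*% t(E)) %*% t(evalBasis(basis, t))
  y <- rbind(signal, matrix(rnorm(nNull * n, sd = 0.05), nNull, n))
  r2 <- runTrajFpcTest(y, t, scale = "log", tigFraction = 0.25,
                       nStages = 2, permutations = 5, seed = 5)
  r3 <- runTrajFpcTest(y, t, scale = "log", tigFraction = 0.25,
                       nStages = 3, permutations = 5, seed = 5)
  expect_true(all(resultTable(r2)$is_tig == (seq_len(nSignal + nNull) <= 50)))
  relDiff <- abs(resultTable(r3)$D - resultTable(r2)$D) /
    pmax(resultTable(r2)$D, 1e-12)
  expect_lt(median(relDiff), 0.01)
})

test_that("SummarizedExperiment input and pseudotime tables are honored", {
  sim <- smallSim()
  counts <- simCounts(sim)
  t <- simPseudotime(sim)
  rSce <- runTrajFpcTest(sim, permutations = 10, seed = 3)
  rMat <- runTrajFpcTest(counts, t, permutations = 10, seed = 3)
  expect_identical(resultTable(rSce), resultTable(rMat))

  ptab <- data.frame(cell_id = rev(colnames(counts)),
                     pseudotime = rev(t) * 7 + 2)  # shuffled + affine
  rTab <- runTrajFpcTest(counts, ptab, permutations = 10, seed = 3)
  # the observed statistic is invariant to cell ordering (permutation draws
  # act on differently ordered columns, so p may differ within resolution)
  expect_equal(resultTable(rTab)$D, resultTable(rMat)$D, tolerance = 1e-10)

  ptabMiss <- ptab[-1, ]
  expect_warning(
    runTrajFpcTest(counts, ptabMiss, permutations = 5, seed = 3),
    "without pseudotime")
  expect_error(
    runTrajFpcTest(counts, data.frame(cell_id = "zzz", pseudotime = 1),
                   permutations = 5),
    "no overlap")
})

test_that("per-permutation basis refitting is available and sane", {
  sim <- smallSim()
  res <- runTrajFpcTest(simCounts(sim)[1:80, ], simPseudotime(sim),
                        permutations = 10, seed = 71, refitBasis = TRUE)
  p <- resultTable(res)$p
  expect_true(all(p >= 0 & p <= 1))
})
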