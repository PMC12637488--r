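test_that("pooled empirical p-values follow the printed counting rule", {
  null <- matrix(c(1, 2, 3, 6), 2, 2)              # B = 2, G = 2
  expect_equal(empiricalPvalue(5, null), 1 / 4)
  expect_equal(empiricalPvalue(0, null), 1)        # everything >= 0
  expect_equal(empiricalPvalue(7, null), 0)        # literal estimator
  expect_equal(empiricalPvalue(7, null, addPseudoCount = TRUE), 1 / 5)
  expect_equal(empiricalPvalue(3, null), 2 / 4)    # inclusive ties
  # per-gene variant compares each gene only against its own column
  expect_equal(empiricalPvalue(c(1.5, 2.5), null, pooled = FALSE),
               c(1 / 2, 1))
})

test_that("empirical p-values equal a brute-force double loop", {
  set.seed(31)
  B <- 7; G <- 23
  null <- matrix(rexp(B * G), B, G)
  null[sample(B * G, 10)] <- null[1, 1]            # inject exact ties
  D <- c(rexp(G - 2), null[2, 3], 0)
  p <- empiricalPvalue(D, null)
  brute <- vapply(D, function(d) {
    cnt <- 0
    for (b in 1:B) for (g in 1:G) if (null[b, g] >= d) cnt <- cnt + 1
    cnt / (B * G)
  }, numeric(1))
  expect_identical(p, brute)
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(p.adjust(rep(1, 5), "BH"), rep(1, 5))
  set.seed(37)
  p <- runif(50)
  # independent textbook implementation
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  for (idx in seq_along(o)) {
    i <- o[idx]
    running <- min(running, p[i] * m / (m - idx + 1))
    q[i] <- running
  }
  expect_equal(p.adjust(p, "BH"), q)
})

test_that("TIG selection keeps the top fraction with a stable tie rule", {
  set.seed(41)
  D <- runif(100)
  sel <- selectTigs(D, 0.25)
  expect_length(sel, 25)
  expect_gte(min(D[sel]), max(D[-sel]))
  expect_equal(sort(selectTigs(D, 1)), 1:100)
  expect_error(selectTigs(numeric(0), 0.2), "empty")
  expect_error(selectTigs(D, 0), "fraction")
  # exact tie at the cutoff: earlier index wins
  Dt <- c(5, 3, 3, 1)
  expect_equal(sort(selectTigs(Dt, 0.5)), c(1, 2))
})

test_that("the no-op permutation reproduces the observed statistics", {
  set.seed(43)
  n <- 40
  t <- seq(0, 1, length.out = n)
  y <- matrix(rnorm(15 * n), 15, n)
  st <- smoothTrajectories(y, t, fpcBasis(8, lambda = 0.01))
  eig <- eigenDecompose(covarianceSurface(st), L = 3)
  D <- distanceStatistic(projectScores(st, eig))
  null <- permutationNull(y, st, eig, perms = list(1:n, sample.int(n)),
                          withResid = TRUE)
  expect_equal(unname(null@stats[1, ]), unname(D), tolerance = 1e-10)
  fb <- fpcFStatistic(st, eig)
  expect_equal(unname(null@resid[1, ]), unname(fb$resid), tolerance = 1e-10)
  # constant (all-zero centered) genes never move under permutation
  y0 <- rbind(rep(0, n), y[1, ])
  st0 <- smoothTrajectories(y0, t, fpcBasis(8, lambda = 0.01))
  null0 <- permutationNull(y0, st0, eig, B = 5, seed = 2)
  expect_equal(unname(null0@stats[, 1]), rep(0, 5))
})

test_that("permutation p-values are uniform for exchangeable noise", {
  set.seed(47)
  n <- 60
  t <- seq(0, 1, length.out = n)
  y <- matrix(rnorm(200 * n), 200, n)
  st <- smoothTrajectories(y, t, fpcBasis(lambda = 0.1))
  eig <- eigenDecompose(covarianceSurface(st), L = 3)
  D <- distanceStatistic(projectScores(st, eig))
  null <- permutationNull(y, st, eig, B = 200, seed = 48)
  p <- empiricalPvalue(D, null)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("the F baseline floors its denominator and zeroes null genes", {
  basis <- fpcBasis()
  E <- orthoOscillationCoefs(basis)
  K <- E %*% diag(c(1, 0.5, 0.25)) %*% t(E)
  eig <- eigenDecompose(
    new("CovarianceSurface", K = K, basis = basis, nGenes = 3L), L = 3)
  # gene exactly inside span(Phi): residual 0, F hits the epsilon ceiling
  inSpan <- trajFromCoef(rbind(2 * E[, 1], 0 * E[, 1]), basis)
  fb <- fpcFStatistic(inSpan, eig, epsilon = 1e-8)
  expect_equal(fb$F[1], fb$D[1] / 1e-8, tolerance = 1e-6)
  expect_equal(fb$F[2], 0)
})
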