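test_that("covariance surface is the averaged coefficient outer product", {
  set.seed(3)
  A <- matrix(rnorm(10 * 10), 10, 10)
  st <- trajFromCoef(A)
  cov <- covarianceSurface(st)
  expect_equal(cov@K, crossprod(A) / 10, ignore_attr = TRUE)
  # sign-invariance: f and -f pairs give the same surface
  cov2 <- covarianceSurface(trajFromCoef(rbind(A, -A)))
  expect_equal(cov2@K, cov@K, tolerance = 1e-12)
  expect_warning(covarianceSurface(trajFromCoef(A[1, , drop = FALSE])),
                 "rank 1")
})

test_that("a rank-1 surface yields the normalized function as eigenpair", {
  basis <- fpcBasis()
  f <- orthoOscillationCoefs(basis)[, 1] * 2      # ||f|| = 2
  cov <- suppressWarnings(covarianceSurface(trajFromCoef(rbind(f))))
  eig <- eigenDecompose(cov)
  expect_equal(length(eig@values), 1L)
  expect_equal(eig@values[1], 4, tolerance = 1e-8)      # ||f||^2
  expect_equal(eig@varExplained, 1, tolerance = 1e-10)
  J <- basisGram(basis)
  align <- abs(drop(crossprod(eig@coefmat[, 1], J %*% (f / 2))))
  expect_equal(align, 1, tolerance = 1e-8)
})

test_that("eigenfunctions are L2-orthonormal and eigenvalues bookkeep variance", {
  set.seed(5)
  st <- trajFromCoef(matrix(rnorm(50 * 10), 50, 10))
  cov <- covarianceSurface(st)
  eig <- eigenDecompose(cov, L = 6)
  J <- basisGram(st@basis)
  expect_equal(crossprod(eig@coefmat, J %*% eig@coefmat), diag(6),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sum of ALL eigenvalues equals the integrated trace of C(t,t)
  tg <- seq(0, 1, length.out = 20001)
  diagC <- rowSums((evalBasis(st@basis, tg) %*% cov@K) *
                     evalBasis(st@basis, tg))
  expect_equal(eig@totalVariance, sum(trapWeights(20001) * diagC),
               tolerance = 1e-6)
})

test_that("eigensystem matches a dense-grid eigendecomposition oracle", {
  basis <- fpcBasis()
  E <- orthoOscillationCoefs(basis)
  w <- c(1, 0.5, 0.25)
  K <- E %*% diag(w) %*% t(E)
  cov <- new("CovarianceSurface", K = K, basis = basis, nGenes = 3L)
  eig <- eigenDecompose(cov, L = 3)
  expect_equal(eig@values, w, tolerance = 1e-8)

  # oracle: 501-point trapezoid quadrature eigenproblem on the dense kernel
  tg <- seq(0, 1, length.out = 501)
  Cd <- evalCovariance(cov, tg)
  sw <- sqrt(trapWeights(501))
  ed <- eigen((Cd * outer(sw, sw) + t(Cd * outer(sw, sw))) / 2,
              symmetric = TRUE)
  expect_equal(eig@values, ed$values[1:3], tolerance = 1e-4)
  Phi <- evalEigenfunctions(eig, tg)
  for (k in 1:3) {
    oracleFn <- ed$vectors[, k] / sw
    err <- min(max(abs(Phi[, k] - oracleFn)), max(abs(Phi[, k] + oracleFn)))
    expect_lt(err, 1e-3 * max(abs(oracleFn)))
  }
})

test_that("component-count rules behave at the edges", {
  basis <- fpcBasis()
  E <- orthoOscillationCoefs(basis)
  K <- E %*% diag(c(1, 0.5, 0.25)) %*% t(E)
  cov <- new("CovarianceSurface", K = K, basis = basis, nGenes = 3L)
  expect_warning(eig <- eigenDecompose(cov, L = 8), "rank")
  expect_lte(length(eig@values), 3L)
  # variance rule: 1/1.75 = 57%, 1.5/1.75 = 86%, so 90% needs L = 3
  expect_equal(length(eigenDecompose(cov, varThreshold = 0.9)@values), 3L)
  expect_equal(length(eigenDecompose(cov, varThreshold = 0.5)@values), 1L)
  # degenerate all-zero surface
  covZ <- new("CovarianceSurface", K = matrix(0, 10, 10), basis = basis,
              nGenes = 2L)
  expect_warning(eigZ <- eigenDecompose(covZ), "no variance")
  expect_equal(eigZ@values, 0)
})

test_that("eigenfunction signs are deterministic", {
  set.seed(9)
  st <- trajFromCoef(matrix(rnorm(40 * 10), 40, 10))
  eig <- eigenDecompose(covarianceSurface(st), L = 4)
  mT <- trajFPC:::.basisMomentT(st@basis)
  for (k in 1:4) {
    s <- sum(eig@coefmat[, k] * mT)
    if (abs(s) > 1e-10) expect_gte(s, 0)
  }
  # flipping input signs leaves the reported eigenfunctions unchanged
  eig2 <- eigenDecompose(covarianceSurface(trajFromCoef(-st@coef)), L = 4)
  expect_equal(eig@coefmat, eig2@coefmat, tolerance = 1e-8)
})
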