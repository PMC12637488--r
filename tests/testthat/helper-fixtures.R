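# Shared fixture builders for the unit tests. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Dense trapezoid quadrature weights on an equally spaced grid.
trapWeights <- function(n) {
  w <- rep(1 / (n - 1), n)
  w[c(1, n)] <- w[c(1, n)] / 2
  w
}

# Smoothed trajectories built directly from given spline coefficients,
# bypassing the fitting step (for projection / eigen tests).
trajFromCoef <- function(coef, basis = fpcBasis(), t = seq(0, 1, 0.01)) {
  new("SmoothedTrajectories", coef = as.matrix(coef), basis = basis,
      geneMeans = rep(0, nrow(coef)),
      constant = rep(FALSE, nrow(coef)), t = t)
}

# Coefficient vectors of the three damped-oscillation curves, least-squares
# projected onto a spline basis and then Gram-Schmidt orthonormalized in
# the L2 metric of that basis.
orthoOscillationCoefs <- function(basis = fpcBasis()) {
  tg <- seq(0, 1, length.out = 401)
  Phi <- t(oscillationBases(tg))                  # 401 x 3
  X <- evalBasis(basis, tg)
  raw <- qr.solve(X, Phi)                         # nbasis x 3
  J <- basisGram(basis)
  for (k in 1:3) {
    if (k > 1) {
      prev <- raw[, seq_len(k - 1), drop = FALSE]
      raw[, k] <- raw[, k] - prev %*% crossprod(prev, J %*% raw[, k])
    }
    raw[, k] <- raw[, k] / sqrt(drop(crossprod(raw[, k], J %*% raw[, k])))
  }
  raw
}

# A small noisy simulated dataset shared by several heavier tests.
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateTrajectoryData(trajSimConfig(
        nGenes = 200, nTdeg = 30, nCells = 100, seed = 42))
    cache
  }
})

simCounts <- function(sim) as.matrix(SummarizedExperiment::assay(sim, "counts"))
simPseudotime <- function(sim) SummarizedExperiment::colData(sim)$pseudotime
simTruth <- function(sim) SummarizedExperiment::rowData(sim)$isTDEG
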