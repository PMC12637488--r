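#' Configuration for the zero-inflated trajectory simulator
#'
#' Defaults reproduce the high zero-inflation study design: 4,000 genes of
#' which 500 are true TDEGs, observed at 500 equally spaced pseudotime
#' points on the unit interval, with negative-binomial dispersion
#' \eqn{\theta = 1} and a Bernoulli dropout indicator that keeps an entry
#' with probability 0.25 (so 75% of entries are zeroed by dropout alone).
#'
#' @param nGenes total gene count G.
#' @param nTdeg number of true TDEGs.
#' @param nCells number of pseudotime points (cells).
#' @param eigenvalueWeights weights \eqn{(\lambda_1, \lambda_2, \lambda_3)}
#'   scaling the three generating score directions.
#' @param nbDispersion NB dispersion \eqn{\theta} (variance
#'   \eqn{\mu + \mu^2/\theta}).
#' @param dropoutKeepProb Bernoulli probability that an entry is kept;
#'   entries with indicator 0 are dropout zeros.
#' @param seed RNG seed for full reproducibility.
#' @param preset convenience override of `dropoutKeepProb`: `"high-zi"`
#'   (0.25, the primary setting), `"moderate-zi"` (0.5), `"low-zi"` (0.75),
#'   `"no-dropout"` (1). The moderate/low values are illustrative presets,
#'   not a published calibration.
#' @return list of class `trajSimConfig`.
#' @export
trajSimConfig <- function(nGenes = 4000L, nTdeg = 500L, nCells = 500L,
                          eigenvalueWeights = c(1, 0.5, 0.25),
                          nbDispersion = 1, dropoutKeepProb = 0.25,
                          seed = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset,
                        c("high-zi", "moderate-zi", "low-zi", "no-dropout"))
    dropoutKeepProb <- c("high-zi" = 0.25, "moderate-zi" = 0.5,
                         "low-zi" = 0.75, "no-dropout" = 1)[[preset]]
  }
  cfg <- list(nGenes = as.integer(nGenes), nTdeg = as.integer(nTdeg),
              nCells = as.integer(nCells),
              eigenvalueWeights = as.numeric(eigenvalueWeights),
              nbDispersion = nbDispersion,
              dropoutKeepProb = dropoutKeepProb,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (cfg$nTdeg > cfg$nGenes) stop("'nTdeg' cannot exceed 'nGenes'")
  if (cfg$nCells < 2L) stop("need at least two pseudotime points")
  if (cfg$nbDispersion <= 0) stop("NB dispersion must be positive")
  if (cfg$dropoutKeepProb <= 0 || cfg$dropoutKeepProb > 1)
    stop("'dropoutKeepProb' must be in (0, 1]")
  if (length(cfg$eigenvalueWeights) != 3L)
    stop("exactly three eigenvalue weights are required")
  class(cfg) <- "trajSimConfig"
  cfg
}

#' Damped-oscillation generating bases
#'
#' The three dynamic patterns driving simulated TDEG mean curves:
#' \deqn{\phi_1(t) = e^{-t/2}\cos(2\pi t),\quad
#'       \phi_2(t) = e^{-t/2}\sin(2\pi t),\quad
#'       \phi_3(t) = e^{-2t}.}
#'
#' @param t pseudotime values in \[0, 1\].
#' @return 3 x `length(t)` matrix, one basis function per row.
#' @export
oscillationBases <- function(t) {
  rbind(phi1 = exp(-t / 2) * cos(2 * pi * t),
        phi2 = exp(-t / 2) * sin(2 * pi * t),
        phi3 = exp(-2 * t))
}

#' Latent mean curves for true TDEGs
#'
#' Draws generating scores \eqn{\xi_{ik} \sim N(0, 1)} and sets
#' \eqn{\mu_i(t_j) = \exp\left(\sum_{k=1}^{3} \lambda_k \xi_{ik}
#' \phi_k(t_j)\right)} with the eigenvalue weights prioritizing the dominant
#' pattern.
#'
#' @param config a [trajSimConfig()].
#' @param t pseudotime grid.
#' @return list with `mu` (nTdeg x length(t)) and `xi` (nTdeg x 3).
#' @export
tdegMeanCurves <- function(config, t) {
  phi <- oscillationBases(t)
  xi <- matrix(rnorm(config$nTdeg * 3L), config$nTdeg, 3L)
  logMu <- (xi * rep(config$eigenvalueWeights, each = config$nTdeg)) %*% phi
  list(mu = exp(logMu), xi = xi)
}

#' Constant latent means for null genes
#'
#' Each non-TDEG receives a single level \eqn{c_i \sim
#' \mathrm{Uniform}(0, m)} used at every pseudotime point, where \eqn{m} is
#' the median of all simulated TDEG mean values (on the natural scale).
#'
#' @param config a [trajSimConfig()].
#' @param tdegMu the TDEG mean matrix.
#' @return numeric vector of `nGenes - nTdeg` constant levels.
#' @export
nontdegMeans <- function(config, tdegMu) {
  m <- if (length(tdegMu)) median(tdegMu) else 1
  runif(config$nGenes - config$nTdeg, min = 0, max = m)
}

#' Zero-inflated negative binomial counts
#'
#' \eqn{W = W^0 Z} with \eqn{W^0 \sim \mathrm{NB}(\mu, \theta)} (mean
#' \eqn{\mu}, variance \eqn{\mu + \mu^2/\theta}) and the dropout indicator
#' \eqn{Z \sim \mathrm{Bernoulli}(p)}; \eqn{Z = 0} is a dropout event, so
#' the keep probability p = 0.25 zeroes 75% of entries in expectation before
#' NB sampling zeros are counted.
#'
#' @param mu matrix (or vector) of positive latent means.
#' @param config a [trajSimConfig()] providing `nbDispersion` and
#'   `dropoutKeepProb`.
#' @return integer matrix of counts with the dimensions of `mu`.
#' @export
zinbCounts <- function(mu, config) {
  if (any(mu < 0)) stop("latent means must be nonnegative")
  w0 <- rnbinom(length(mu), size = config$nbDispersion, mu = as.numeric(mu))
  z <- rbinom(length(mu), 1L, config$dropoutKeepProb)
  counts <- w0 * z
  if (is.matrix(mu)) dim(counts) <- dim(mu)
  counts
}

#' Simulate a zero-inflated trajectory scRNA-seq dataset
#'
#' Assembles the equally spaced pseudotime grid, TDEG mean curves, constant
#' null-gene means, and ZINB counts into a `SingleCellExperiment` carrying
#' ground truth: assays `counts` and `mu`, `colData$pseudotime`,
#' `rowData$isTDEG`, and the generating scores plus configuration in
#' `metadata`. True TDEGs occupy the first `nTdeg` rows. The draw order is
#' fixed (scores, null levels, NB counts, dropout indicators), so a seeded
#' configuration is fully reproducible.
#'
#' @param config a [trajSimConfig()].
#' @return A `SingleCellExperiment` with ground-truth annotation.
#' @examples
#' sim <- simulateTrajectoryData(trajSimConfig(
#'   nGenes = 50, nTdeg = 10, nCells = 40, seed = 7))
#' mean(SummarizedExperiment::assay(sim, "counts") == 0)  # high sparsity
#' @export
simulateTrajectoryData <- function(config = trajSimConfig()) {
  stopifnot(inherits(config, "trajSimConfig"))
  if (!is.na(config$seed)) set.seed(config$seed)
  t <- seq(0, 1, length.out = config$nCells)

  if (config$nTdeg > 0L) {
    td <- tdegMeanCurves(config, t)
  } else {
    td <- list(mu = matrix(0, 0L, config$nCells), xi = matrix(0, 0L, 3L))
  }
  cNull <- nontdegMeans(config, td$mu)
  mu <- rbind(td$mu,
              matrix(cNull, nrow = length(cNull), ncol = config$nCells))
  counts <- zinbCounts(mu, config)

  geneIds <- sprintf("gene%04d", seq_len(config$nGenes))
  cellIds <- sprintf("cell%04d", seq_len(config$nCells))
  dimnames(counts) <- dimnames(mu) <- list(geneIds, cellIds)
  isTdeg <- seq_len(config$nGenes) <= config$nTdeg
  rownames(td$xi) <- geneIds[isTdeg][seq_len(nrow(td$xi))]

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts, mu = mu),
    colData = S4Vectors::DataFrame(pseudotime = t, row.names = cellIds),
    rowData = S4Vectors::DataFrame(isTDEG = isTdeg, row.names = geneIds),
    metadata = list(xiTrue = td$xi, config = config)
  )
}
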