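#' @import methods
#' @importFrom stats p.adjust rnorm runif rbinom rnbinom sd var quantile median ks.test
#' @importFrom utils head read.table write.table packageVersion
NULL

#' B-spline basis for trajectory smoothing
#'
#' Describes the spline system on the unit pseudotime interval used to
#' represent gene expression trajectories: number of basis functions, spline
#' order (degree + 1), interior knot positions, the derivative order that the
#' roughness penalty integrates, and the penalty weight \eqn{\lambda}.
#'
#' @slot nbasis integer, number of B-spline basis functions.
#' @slot order integer, spline order (4 = cubic).
#' @slot knots numeric, interior knots strictly inside (0, 1), nondecreasing.
#' @slot penaltyOrder integer, derivative order penalized (2 = curvature).
#' @slot lambda numeric, roughness penalty weight; `NA` means "choose by
#'   generalized cross-validation when smoothing".
#'
#' @seealso [fpcBasis()] for the user-facing constructor.
#' @exportClass FpcBasis
setClass("FpcBasis",
  representation(
    nbasis = "integer",
    order = "integer",
    knots = "numeric",
    penaltyOrder = "integer",
    lambda = "numeric"
  )
)

setValidity("FpcBasis", function(object) {
  msg <- NULL
  if (length(object@nbasis) != 1L || object@nbasis < object@order)
    msg <- c(msg, "'nbasis' must be a single integer >= 'order'")
  if (length(object@order) != 1L || object@order < 2L)
    msg <- c(msg, "'order' must be a single integer >= 2")
  if (length(object@knots) != object@nbasis - object@order)
    msg <- c(msg, "need exactly nbasis - order interior knots")
  if (length(object@knots) &&
      (any(object@knots <= 0) || any(object@knots >= 1) ||
       is.unsorted(object@knots)))
    msg <- c(msg, "interior knots must be nondecreasing and strictly inside (0, 1)")
  if (length(object@penaltyOrder) != 1L || object@penaltyOrder < 1L ||
      object@penaltyOrder >= object@order)
    msg <- c(msg, "'penaltyOrder' must be in [1, order - 1]")
  if (length(object@lambda) != 1L || (!is.na(object@lambda) && object@lambda < 0))
    msg <- c(msg, "'lambda' must be a single value >= 0 (or NA for GCV)")
  if (is.null(msg)) TRUE else msg
})

#' Penalized-spline representation of gene trajectories
#'
#' Per-gene B-spline coefficients for the smoothed, centered log-expression
#' functions of pseudotime, together with the basis that interprets them, the
#' per-gene centering constants removed before smoothing, and a flag marking
#' genes that were constant across cells.
#'
#' @slot coef numeric matrix, genes x nbasis spline coefficients.
#' @slot basis [FpcBasis-class] with the `lambda` actually used.
#' @slot geneMeans numeric, per-gene centering constants on the log scale.
#' @slot constant logical, `TRUE` for genes constant across all cells.
#' @slot t numeric, the pseudotime grid (rescaled to \[0, 1\]) the fit used.
#'
#' @exportClass SmoothedTrajectories
setClass("SmoothedTrajectories",
  representation(
    coef = "matrix",
    basis = "FpcBasis",
    geneMeans = "numeric",
    constant = "logical",
    t = "numeric"
  )
)

setValidity("SmoothedTrajectories", function(object) {
  msg <- NULL
  if (ncol(object@coef) != object@basis@nbasis)
    msg <- c(msg, "coefficient columns must match basis size")
  if (!all(is.finite(object@coef)))
    msg <- c(msg, "spline coefficients must be finite")
  if (length(object@geneMeans) != nrow(object@coef))
    msg <- c(msg, "one centering constant per gene required")
  if (length(object@constant) != nrow(object@coef))
    msg <- c(msg, "one constant-gene flag per gene required")
  if (is.null(msg)) TRUE else msg
})

#' Pseudotime covariance surface
#'
#' The across-gene covariance kernel \eqn{C(s, t)} of the smoothed, centered
#' trajectories, represented by its coefficient matrix in the B-spline tensor
#' basis: \eqn{C(s, t) = B(s)' K B(t)}.
#'
#' @slot K symmetric nbasis x nbasis coefficient matrix.
#' @slot basis the [FpcBasis-class] of the tensor representation.
#' @slot nGenes integer, number of genes averaged into the surface.
#'
#' @exportClass CovarianceSurface
setClass("CovarianceSurface",
  representation(K = "matrix", basis = "FpcBasis", nGenes = "integer")
)

setValidity("CovarianceSurface", function(object) {
  msg <- NULL
  if (nrow(object@K) != ncol(object@K) ||
      nrow(object@K) != object@basis@nbasis)
    msg <- c(msg, "'K' must be square with dimension equal to the basis size")
  if (max(abs(object@K - t(object@K))) > 1e-8 * max(1, max(abs(object@K))))
    msg <- c(msg, "'K' must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' Eigensystem of the pseudotime covariance operator
#'
#' Leading eigenfunctions \eqn{\Phi_k} (as B-spline coefficient vectors,
#' orthonormal in the L2 inner product) and eigenvalues \eqn{\lambda_k} of the
#' covariance operator, with variance bookkeeping.
#'
#' @slot coefmat nbasis x L matrix; column k holds the spline coefficients of
#'   eigenfunction \eqn{\Phi_k}.
#' @slot values numeric, retained eigenvalues, sorted descending, >= 0.
#' @slot varExplained numeric, cumulative fraction of total variance captured
#'   by the leading components.
#' @slot totalVariance numeric, integrated trace of the covariance surface.
#' @slot basis the [FpcBasis-class] shared with the covariance surface.
#'
#' @exportClass EigenSystem
setClass("EigenSystem",
  representation(
    coefmat = "matrix",
    values = "numeric",
    varExplained = "numeric",
    totalVariance = "numeric",
    basis = "FpcBasis"
  )
)

setValidity("EigenSystem", function(object) {
  msg <- NULL
  if (ncol(object@coefmat) != length(object@values))
    msg <- c(msg, "one eigenvalue per eigenfunction required")
  if (is.unsorted(rev(object@values)))
    msg <- c(msg, "eigenvalues must be sorted in decreasing order")
  if (any(object@values < -1e-10))
    msg <- c(msg, "eigenvalues must be nonnegative")
  if (length(object@varExplained) != length(object@values) ||
      is.unsorted(object@varExplained) ||
      any(object@varExplained > 1 + 1e-8))
    msg <- c(msg, "'varExplained' must be nondecreasing and <= 1")
  if (is.null(msg)) TRUE else msg
})

#' Permutation null distribution of trajectory statistics
#'
#' Per-gene statistics recomputed after shuffling pseudotime labels across
#' cells, with the eigenbasis held fixed at its observed-data estimate.
#'
#' @slot stats B x G matrix of null distance statistics \eqn{D_g^{(b)}}.
#' @slot resid B x G matrix of null within-trajectory residual norms (only
#'   populated when the functional F baseline was requested; otherwise a
#'   0 x 0 matrix).
#' @slot B integer, permutation count.
#' @slot seed integer (or NA), RNG seed used to draw the permutations.
#'
#' @exportClass PermutationNull
setClass("PermutationNull",
  representation(stats = "matrix", resid = "matrix", B = "integer",
                 seed = "integer")
)

setValidity("PermutationNull", function(object) {
  msg <- NULL
  if (nrow(object@stats) != object@B)
    msg <- c(msg, "'stats' must have one row per permutation")
  if (any(object@stats < -1e-12))
    msg <- c(msg, "null statistics must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Result of the trajectory FPC differential-expression test
#'
#' Per-gene distance statistics, pooled-permutation p-values, BH-FDR adjusted
#' values and TDEG / trajectory-informative-gene calls, plus the refined
#' eigensystem and the configuration needed to reproduce the run.
#'
#' @slot table data.frame with columns `gene_id`, `D`, `p`, `q`, `is_tig`,
#'   `is_tdeg`, `constant` and, when the baseline was requested, `F_stat`,
#'   `p_fpcf`.
#' @slot eigenSystem the refined [EigenSystem-class] the final statistics use.
#' @slot scores genes x L matrix of FPC scores on the refined eigenbasis.
#' @slot stage1 list with the stage-1 (all-gene) eigenvalues and D.
#' @slot config list of all tuning parameters and the seed.
#'
#' @exportClass TrajFpcResult
setClass("TrajFpcResult",
  representation(
    table = "data.frame",
    eigenSystem = "EigenSystem",
    scores = "matrix",
    stage1 = "list",
    config = "list"
  )
)

#' Benchmark report for a trajectory DE method
#'
#' Replicate-level operating characteristics of a method on simulated
#' trajectory data with known TDEG labels.
#'
#' @slot alphaGrid numeric, nominal significance levels.
#' @slot tier replicates x alpha matrix of observed type-I error rates.
#' @slot power replicates x alpha matrix of observed power.
#' @slot auc numeric, per-replicate ROC-AUC.
#' @slot fpCount numeric, false positives at alpha = 0.05 per replicate.
#' @slot nNull,nSignal integer, null / true-TDEG gene counts per dataset.
#' @slot failed integer, number of replicates on which the method errored.
#'
#' @exportClass TrajBenchmark
setClass("TrajBenchmark",
  representation(
    alphaGrid = "numeric",
    tier = "matrix",
    power = "matrix",
    auc = "numeric",
    fpCount = "numeric",
    nNull = "integer",
    nSignal = "integer",
    failed = "integer"
  )
)
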