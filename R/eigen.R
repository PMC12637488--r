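#' Estimate the pseudotime covariance surface
#'
#' Averages outer products of the smoothed, centered trajectories:
#' \deqn{C(s, t) = \frac{1}{G} \sum_i f_i(s) f_i(t),}
#' represented in the B-spline tensor basis as \eqn{K = A'A / G} for the
#' gene x nbasis coefficient matrix \eqn{A}.
#'
#' @param smoothed a [SmoothedTrajectories-class].
#' @param genes optional index (integer/logical/character) restricting the
#'   gene set, e.g. trajectory-informative genes for the refinement stage.
#' @return A [CovarianceSurface-class].
#' @export
covarianceSurface <- function(smoothed, genes = NULL) {
  stopifnot(is(smoothed, "SmoothedTrajectories"))
  A <- smoothed@coef
  if (!is.null(genes)) A <- A[genes, , drop = FALSE]
  if (nrow(A) < 1L) stop("covariance needs at least one gene")
  if (nrow(A) == 1L)
    warning("single-gene covariance surface is rank 1; eigenanalysis will ",
            "be degenerate")
  K <- crossprod(A) / nrow(A)
  new("CovarianceSurface", K = (K + t(K)) / 2, basis = smoothed@basis,
      nGenes = nrow(A))
}

#' Evaluate a covariance surface on a grid
#'
#' @param cov a [CovarianceSurface-class].
#' @param s,t evaluation points in \[0, 1\] (`t` defaults to `s`).
#' @return `length(s)` x `length(t)` matrix of \eqn{C(s, t)}.
#' @export
evalCovariance <- function(cov, s, t = s) {
  stopifnot(is(cov, "CovarianceSurface"))
  Bs <- evalBasis(cov@basis, s)
  Bt <- evalBasis(cov@basis, t)
  Bs %*% cov@K %*% t(Bt)
}

#' Solve the functional eigenproblem of the covariance operator
#'
#' Finds eigenfunction/eigenvalue pairs of
#' \eqn{\int C(s, t) \Phi_k(s) ds = \lambda_k \Phi_k(t)} in the B-spline
#' basis. Writing \eqn{\Phi_k(t) = B(t)' b_k} and \eqn{J = \int B B'},
#' the problem becomes \eqn{K J b = \lambda b}; it is symmetrized with the
#' Cholesky factor of \eqn{J} so that a standard symmetric eigensolver
#' applies and the returned coefficient vectors are orthonormal in the L2
#' inner product. All inner products are exact in the basis (no grid
#' quadrature).
#'
#' Signs are fixed deterministically: \eqn{\int \Phi_k(t)\, t\, dt \ge 0},
#' with ties resolved by the sign of \eqn{\Phi_k(0)}.
#'
#' @param cov a [CovarianceSurface-class].
#' @param L fixed number of components; overrides the variance rule.
#' @param varThreshold retain the smallest L whose cumulative variance
#'   fraction reaches this value (default 0.90).
#' @param maxL cap on the retained component count.
#' @return An [EigenSystem-class].
#' @export
eigenDecompose <- function(cov, L = NULL, varThreshold = 0.9, maxL = 10L) {
  stopifnot(is(cov, "CovarianceSurface"))
  basis <- cov@basis
  J <- basisGram(basis)
  R <- chol(J)                               # J = R'R
  S <- R %*% cov@K %*% t(R)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)

  if (total <= 1e-14) {
    warning("covariance surface has no variance; returning a degenerate ",
            "single zero component")
    b <- backsolve(R, e$vectors[, 1L, drop = FALSE])
    return(new("EigenSystem", coefmat = b, values = 0, varExplained = 1,
               totalVariance = 0, basis = basis))
  }

  rank <- sum(vals > 1e-12 * vals[1L])
  if (is.null(L)) {
    cumfrac <- cumsum(vals) / total
    L <- which(cumfrac >= varThreshold)[1L]
    if (is.na(L)) L <- length(vals)
    L <- min(L, maxL)
  } else if (L > rank) {
    warning("requested ", L, " components but numerical rank is ", rank,
            "; truncating")
    L <- rank
  }
  L <- max(1L, min(as.integer(L), length(vals)))

  Bcoef <- backsolve(R, e$vectors[, seq_len(L), drop = FALSE])
  mT <- .basisMomentT(basis)
  B0 <- drop(evalBasis(basis, 0))
  for (k in seq_len(L)) {
    s <- sum(Bcoef[, k] * mT)
    if (abs(s) < 1e-10) s <- sum(Bcoef[, k] * B0)
    if (s < 0) Bcoef[, k] <- -Bcoef[, k]
  }
  new("EigenSystem", coefmat = Bcoef, values = vals[seq_len(L)],
      varExplained = cumsum(vals[seq_len(L)]) / total,
      totalVariance = total, basis = basis)
}

#' Evaluate eigenfunctions (or their derivatives) on a grid
#'
#' @param eig an [EigenSystem-class].
#' @param t evaluation points in \[0, 1\].
#' @param deriv derivative order.
#' @return `length(t)` x L matrix, column k giving \eqn{\Phi_k^{(d)}(t)}.
#' @export
evalEigenfunctions <- function(eig, t, deriv = 0L) {
  stopifnot(is(eig, "EigenSystem"))
  evalBasis(eig@basis, t, deriv = deriv) %*% eig@coefmat
}

#' @rdname EigenSystem-class
#' @param object an `EigenSystem`.
#' @export
setMethod("show", "EigenSystem", function(object) {
  L <- length(object@values)
  cat("EigenSystem:", L, "component(s) on", object@basis@nbasis,
      "B-splines\n")
  cat("  eigenvalues:", paste(signif(object@values, 4), collapse = " "), "\n")
  cat("  cumulative variance:",
      paste(sprintf("%.1f%%", 100 * object@varExplained), collapse = " "),
      "\n")
})

# Internal: number of retained components.
nComponents <- function(eig) length(eig@values)

.sameBasis <- function(a, b) {
  a@nbasis == b@nbasis && a@order == b@order &&
    length(a@knots) == length(b@knots) &&
    (length(a@knots) == 0 || max(abs(a@knots - b@knots)) < 1e-12)
}

#' Project smoothed trajectories onto the eigenbasis
#'
#' Computes FPC scores \eqn{\xi_{ik} = \int f_i(t) \Phi_k(t) dt} exactly via
#' the basis Gram matrix. The rank-L reconstruction
#' \eqn{\sum_k \xi_{ik}\Phi_k} is the L2-optimal approximation of \eqn{f_i}
#' within the span of the retained eigenfunctions.
#'
#' @param smoothed a [SmoothedTrajectories-class].
#' @param eig an [EigenSystem-class] sharing the same basis.
#' @return genes x L numeric matrix of scores.
#' @export
projectScores <- function(smoothed, eig) {
  stopifnot(is(smoothed, "SmoothedTrajectories"), is(eig, "EigenSystem"))
  if (!.sameBasis(smoothed@basis, eig@basis))
    stop("smoothed trajectories and eigensystem use different bases")
  J <- basisGram(smoothed@basis)
  xi <- smoothed@coef %*% J %*% eig@coefmat
  rownames(xi) <- rownames(smoothed@coef)
  colnames(xi) <- paste0("FPC", seq_len(ncol(xi)))
  xi
}
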