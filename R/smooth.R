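#' Smooth gene trajectories with roughness-penalized B-splines
#'
#' Fits, for every gene, the penalized least-squares spline
#' \deqn{\min_c \sum_j (y_j - B(t_j)'c)^2 + \lambda \int (f^{(m)})^2}
#' Because all genes share one pseudotime grid, the smoother matrix
#' \eqn{(X'X + \lambda P)^{-1} X'} is factored once and applied to every gene
#' by matrix multiplication; results are identical to per-gene solves.
#'
#' When `basis@lambda` is `NA`, the penalty weight is chosen by generalized
#' cross-validation pooled across genes over a log-spaced grid.
#'
#' @param y genes x cells matrix of centered log expression.
#' @param t pseudotime per cell; rescaled to \[0, 1\] internally.
#' @param basis an [FpcBasis-class]; its `lambda` (or GCV) sets the penalty.
#' @param geneMeans,constant optional per-gene centering constants and
#'   constant-gene flags from [logCenterExpression()]; defaults assume the
#'   input is already centered.
#' @param lambdaGrid GCV search grid (ignored when `lambda` is fixed).
#' @return A [SmoothedTrajectories-class] object whose basis records the
#'   `lambda` actually used.
#' @export
smoothTrajectories <- function(y, t, basis = fpcBasis(),
                               geneMeans = NULL, constant = NULL,
                               lambdaGrid = 10^seq(-6, 2, length.out = 25)) {
  y <- as.matrix(y)
  t <- .rescalePseudotime(t)
  if (length(t) != ncol(y))
    stop("need one pseudotime value per cell (column)")
  nDistinct <- length(unique(t))
  if (nDistinct < basis@nbasis)
    warning("only ", nDistinct, " distinct pseudotime values for ",
            basis@nbasis, " basis functions; consider a smaller basis or ",
            "larger penalty")
  X <- evalBasis(basis, t)
  XtX <- crossprod(X)
  P <- basisGram(basis, deriv = basis@penaltyOrder)
  U <- y %*% X
  n <- ncol(y)

  solveCoef <- function(lambda) {
    A <- XtX + lambda * P
    ok <- TRUE
    M <- tryCatch(chol2inv(chol(A)), error = function(e) {
      ok <<- FALSE
      NULL
    })
    if (!ok)
      stop("normal equations are singular at lambda = ", lambda,
           "; raise the penalty or reduce 'nbasis'")
    M
  }

  lambda <- basis@lambda
  if (is.na(lambda)) {
    yss <- sum(y^2)
    gcv <- vapply(lambdaGrid, function(l) {
      M <- solveCoef(l)
      Coef <- U %*% M
      rss <- yss - 2 * sum(U * Coef) + sum((Coef %*% XtX) * Coef)
      df <- sum(M * XtX)          # tr(X (X'X + lP)^-1 X') = tr(M X'X)
      (rss / (n * nrow(y))) / (1 - df / n)^2
    }, numeric(1))
    lambda <- lambdaGrid[which.min(gcv)]
  }
  Coef <- U %*% solveCoef(lambda)

  basis@lambda <- lambda
  if (is.null(geneMeans)) geneMeans <- rep(0, nrow(y))
  if (is.null(constant))
    constant <- apply(y, 1L, function(r) max(r) - min(r) == 0)
  rownames(Coef) <- rownames(y)
  new("SmoothedTrajectories", coef = Coef, basis = basis,
      geneMeans = as.numeric(geneMeans), constant = constant, t = t)
}

#' Evaluate smoothed trajectories on a pseudotime grid
#'
#' @param object a [SmoothedTrajectories-class].
#' @param t evaluation points in \[0, 1\]; defaults to the fitted grid.
#' @param addMeans add back the per-gene centering constants.
#' @return genes x `length(t)` matrix of fitted values.
#' @export
fittedTrajectories <- function(object, t = NULL, addMeans = FALSE) {
  stopifnot(is(object, "SmoothedTrajectories"))
  if (is.null(t)) t <- object@t
  fit <- object@coef %*% t(evalBasis(object@basis, t))
  if (addMeans) fit <- fit + object@geneMeans
  fit
}

#' @describeIn smoothTrajectories display a fit summary
#' @param object a `SmoothedTrajectories`.
#' @export
setMethod("show", "SmoothedTrajectories", function(object) {
  cat("SmoothedTrajectories:", nrow(object@coef), "genes x",
      length(object@t), "cells\n")
  cat("  basis:", object@basis@nbasis, "B-splines (order",
      paste0(object@basis@order, "),"), "lambda =",
      format(object@basis@lambda), "\n")
  nc <- sum(object@constant)
  if (nc) cat("  constant genes flagged:", nc, "\n")
})
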