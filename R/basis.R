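#' Construct a B-spline basis on the unit pseudotime interval
#'
#' Builds the spline system used to represent gene expression trajectories.
#' Interior knots are equally spaced by default, so `nbasis = order +
#' length(knots)`. The default (10 cubic B-splines, curvature penalty) is
#' flexible enough for damped-oscillation expression patterns while keeping
#' the downstream eigenproblem small.
#'
#' @param nbasis number of basis functions (>= `order`).
#' @param order spline order, i.e. polynomial degree + 1; 4 gives cubics.
#' @param knots interior knot positions strictly inside (0, 1); defaults to
#'   `nbasis - order` equally spaced knots.
#' @param penaltyOrder derivative order integrated by the roughness penalty.
#' @param lambda roughness penalty weight; `NA` (default) defers the choice
#'   to generalized cross-validation at smoothing time.
#'
#' @return An [FpcBasis-class] object.
#' @examples
#' b <- fpcBasis(10)
#' rowSums(evalBasis(b, seq(0, 1, 0.1)))  # partition of unity
#' @export
fpcBasis <- function(nbasis = 10L, order = 4L, knots = NULL,
                     penaltyOrder = 2L, lambda = NA_real_) {
  nbasis <- as.integer(nbasis)
  order <- as.integer(order)
  if (nbasis < order)
    stop("'nbasis' (", nbasis, ") must be at least the spline order (",
         order, ")")
  nInterior <- nbasis - order
  if (is.null(knots)) {
    knots <- if (nInterior > 0)
      seq(0, 1, length.out = nInterior + 2L)[-c(1L, nInterior + 2L)]
    else numeric(0)
  }
  new("FpcBasis", nbasis = nbasis, order = order, knots = as.numeric(knots),
      penaltyOrder = as.integer(penaltyOrder), lambda = as.numeric(lambda))
}

.fullKnots <- function(basis) {
  c(rep(0, basis@order), basis@knots, rep(1, basis@order))
}

#' Evaluate basis functions (or their derivatives)
#'
#' @param basis an [FpcBasis-class].
#' @param t evaluation points in \[0, 1\].
#' @param deriv derivative order (0 = the functions themselves).
#' @return `length(t)` x `nbasis` design matrix.
#' @export
evalBasis <- function(basis, t, deriv = 0L) {
  stopifnot(is(basis, "FpcBasis"))
  if (any(!is.finite(t)) || any(t < -1e-12) || any(t > 1 + 1e-12))
    stop("evaluation points must be finite and inside [0, 1]")
  t <- pmin(pmax(t, 0), 1)
  # derivatives at the right boundary use the left limit (splineDesign
  # would otherwise return 0 at t = 1)
  if (deriv > 0L) t[t == 1] <- 1 - 1e-12
  splines::splineDesign(.fullKnots(basis), x = t, ord = basis@order,
                        derivs = rep(as.integer(deriv), length(t)))
}

# Gauss-Legendre rule over every knot span; `npts` points are exact for
# polynomials up to degree 2*npts - 1, which covers products of spline
# derivatives for cubic (and most practical) orders.
.quadRule <- function(basis, npts = 8L) {
  breaks <- unique(c(0, basis@knots, 1))
  nodes <- numeric(0)
  weights <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    gl <- pracma::gaussLegendre(npts, breaks[i], breaks[i + 1L])
    nodes <- c(nodes, gl$x)
    weights <- c(weights, gl$w)
  }
  list(nodes = nodes, weights = weights)
}

#' Inner-product (Gram) matrix of basis derivatives
#'
#' Computes \eqn{\int_0^1 B^{(d)}(t) B^{(d)}(t)' dt} by per-span
#' Gauss-Legendre quadrature, which is exact for piecewise-polynomial
#' integrands. `deriv = 0` gives the L2 Gram matrix used for all functional
#' inner products; `deriv = basis@penaltyOrder` gives the roughness penalty
#' matrix.
#'
#' @param basis an [FpcBasis-class].
#' @param deriv derivative order applied to both factors.
#' @return Symmetric `nbasis` x `nbasis` matrix.
#' @export
basisGram <- function(basis, deriv = 0L) {
  q <- .quadRule(basis)
  Bq <- evalBasis(basis, q$nodes, deriv = deriv)
  G <- crossprod(Bq, Bq * q$weights)
  (G + t(G)) / 2
}

# \int B(t) t dt, used by the eigenfunction sign convention.
.basisMomentT <- function(basis) {
  q <- .quadRule(basis)
  Bq <- evalBasis(basis, q$nodes)
  drop(crossprod(Bq, q$weights * q$nodes))
}

#' @describeIn fpcBasis display a basis summary
#' @param object an `FpcBasis`.
#' @export
setMethod("show", "FpcBasis", function(object) {
  cat("FpcBasis:", object@nbasis, "B-splines of order", object@order,
      "on [0, 1]\n")
  cat("  interior knots:", if (length(object@knots))
    paste(signif(object@knots, 4), collapse = " ") else "(none)", "\n")
  cat("  penalty: derivative order", object@penaltyOrder, "| lambda:",
      if (is.na(object@lambda)) "GCV" else format(object@lambda), "\n")
})
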