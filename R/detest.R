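#' Squared-norm distance statistic
#'
#' \eqn{D_i = \sum_k \xi_{ik}^2}: the squared L2 distance between the zero
#' function and gene i's trajectory projected onto the span of the retained
#' eigenfunctions. Large values indicate strong pseudo-temporal variation.
#'
#' @param xi genes x L score matrix from [projectScores()].
#' @return numeric vector of per-gene statistics, >= 0.
#' @export
distanceStatistic <- function(xi) {
  xi <- as.matrix(xi)
  if (any(!is.finite(xi))) stop("scores must be finite")
  rowSums(xi^2)
}

#' Permutation null distribution of the distance statistic
#'
#' Shuffles the pseudotime labels across cells B times and recomputes the
#' per-gene statistics. Because the smoother acts on a fixed grid, permuting
#' labels is equivalent to applying the fixed smoother matrix to
#' column-permuted expression; the eigenfunctions are held fixed at their
#' observed-data estimates, so each permutation is a single matrix product.
#' Set `refitBasis = TRUE` to re-estimate the covariance surface and
#' eigensystem inside every permutation instead (slower; the retained L is
#' kept equal to the observed one).
#'
#' @param y genes x cells centered log-expression matrix.
#' @param smoothed the observed-data [SmoothedTrajectories-class] (fixes the
#'   pseudotime grid and penalty).
#' @param eig the observed-data [EigenSystem-class].
#' @param B number of permutations.
#' @param seed optional RNG seed for reproducible permutations.
#' @param withResid also record null within-trajectory residual norms, needed
#'   by the functional F baseline.
#' @param refitBasis re-run the eigendecomposition per permutation.
#' @param tigs gene subset used for covariance re-estimation when
#'   `refitBasis = TRUE` (defaults to all genes).
#' @param perms optional list of explicit cell permutations (integer vectors
#'   of length `ncol(y)`) overriding the random draws; `B` is then taken
#'   from its length.
#' @return A [PermutationNull-class] with a B x G matrix of null statistics.
#' @export
permutationNull <- function(y, smoothed, eig, B = 100L, seed = NULL,
                            withResid = FALSE, refitBasis = FALSE,
                            tigs = NULL, perms = NULL) {
  stopifnot(is(smoothed, "SmoothedTrajectories"), is(eig, "EigenSystem"))
  if (!is.null(perms)) B <- length(perms)
  B <- as.integer(B)
  y <- as.matrix(y)
  if (B < 1L || nrow(y) < 1L)
    stop("need at least one permutation and one gene")
  n <- ncol(y)
  if (length(smoothed@t) != n)
    stop("expression and smoothed trajectories disagree on cell count")
  if (!is.null(seed)) set.seed(seed)

  basis <- smoothed@basis
  X <- evalBasis(basis, smoothed@t)
  P <- basisGram(basis, deriv = basis@penaltyOrder)
  M <- chol2inv(chol(crossprod(X) + basis@lambda * P))
  W <- X %*% M                              # n x nbasis smoother factor
  J <- basisGram(basis)
  Tm <- W %*% (J %*% eig@coefmat)           # n x L projection operator
  L <- nComponents(eig)

  D <- matrix(0, B, nrow(y))
  resid <- if (withResid) matrix(0, B, nrow(y)) else matrix(0, 0, 0)
  needCoef <- withResid || refitBasis
  for (b in seq_len(B)) {
    perm <- if (is.null(perms)) sample.int(n) else perms[[b]]
    yp <- y[, perm, drop = FALSE]
    if (needCoef) {
      Coef <- yp %*% W
      if (refitBasis) {
        A <- if (is.null(tigs)) Coef else Coef[tigs, , drop = FALSE]
        Kb <- crossprod(A) / nrow(A)
        covB <- new("CovarianceSurface", K = (Kb + t(Kb)) / 2,
                    basis = basis, nGenes = nrow(A))
        eigB <- suppressWarnings(eigenDecompose(covB, L = L))
        xiB <- Coef %*% J %*% eigB@coefmat
      } else {
        xiB <- Coef %*% (J %*% eig@coefmat)
      }
      D[b, ] <- rowSums(xiB^2)
      if (withResid) {
        normsq <- rowSums((Coef %*% J) * Coef)
        resid[b, ] <- pmax(normsq - D[b, ], 0)
      }
    } else {
      D[b, ] <- rowSums((yp %*% Tm)^2)
    }
  }
  new("PermutationNull", stats = D, resid = resid, B = B,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Pooled permutation p-values
#'
#' Implements the pooled empirical p-value
#' \deqn{p_i = \frac{1}{B G} \sum_{b=1}^{B} \sum_{g=1}^{G}
#'       I\{D_g^{(b)} \ge D_i\},}
#' counting ties inclusively. Pooling across genes assumes cross-gene
#' exchangeability of the null statistic and yields p-value resolution
#' 1/(BG). With `pooled = FALSE` each gene is compared only against its own
#' B permutations. The literal estimator can return 0 for a statistic larger
#' than every null draw; `addPseudoCount = TRUE` switches to
#' (1 + count)/(1 + N) for strictly positive p-values.
#'
#' @param D observed per-gene statistics.
#' @param null a [PermutationNull-class] (or a B x G matrix).
#' @param pooled pool null statistics across genes (default) or per gene.
#' @param addPseudoCount use the (1 + count)/(1 + N) guard.
#' @return numeric vector of p-values in \[0, 1\].
#' @export
empiricalPvalue <- function(D, null, pooled = TRUE, addPseudoCount = FALSE) {
  stats <- if (is(null, "PermutationNull")) null@stats else as.matrix(null)
  if (length(stats) == 0L) stop("permutation null is empty")
  adjust <- function(count, N)
    if (addPseudoCount) (1 + count) / (1 + N) else count / N
  if (pooled) {
    pool <- sort(as.numeric(stats))
    N <- length(pool)
    # count(pool >= d) = N - count(pool < d)
    cnt <- N - findInterval(D, pool, left.open = TRUE)
    adjust(cnt, N)
  } else {
    if (ncol(stats) != length(D))
      stop("per-gene null requires one column per gene")
    vapply(seq_along(D), function(i)
      adjust(sum(stats[, i] >= D[i]), nrow(stats)), numeric(1))
  }
}

#' Select trajectory-informative genes
#'
#' Returns the indices of the `ceiling(fraction * G)` genes with the largest
#' distance statistic. Ties at the cutoff are broken by stable input order
#' (the earlier-indexed gene is retained), making the selection deterministic.
#'
#' @param D per-gene distance statistics.
#' @param fraction fraction of genes to keep, in (0, 1\]; the default 0.25 is
#'   the midpoint of the recommended top 20-30% band.
#' @return integer vector of selected gene indices (in decreasing-D order).
#' @export
selectTigs <- function(D, fraction = 0.25) {
  if (length(D) == 0L) stop("cannot select genes from an empty set")
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  k <- ceiling(fraction * length(D))
  order(D, decreasing = TRUE)[seq_len(k)]
}

#' Functional F baseline statistic
#'
#' The classical functional F-type statistic contrasting between- and
#' within-trajectory variation: \eqn{F_i = D_i / (r_i + \epsilon)}, where
#' \eqn{r_i = \|f_i\|^2 - D_i} is the squared L2 distance between the
#' smoothed gene and its rank-L projection. When a gene's profile is
#' dominated by zeros the residual can be tiny, so a few nonzero points
#' produce spuriously large F values; the floor \eqn{\epsilon} merely keeps
#' the ratio finite. This baseline is provided for comparison and is
#' flagged experimental.
#'
#' @param smoothed a [SmoothedTrajectories-class].
#' @param eig an [EigenSystem-class].
#' @param xi optional precomputed scores.
#' @param epsilon denominator floor.
#' @return list with `F` (per-gene statistic), `D`, and `resid`.
#' @export
fpcFStatistic <- function(smoothed, eig, xi = NULL, epsilon = 1e-8) {
  if (is.null(xi)) xi <- projectScores(smoothed, eig)
  D <- distanceStatistic(xi)
  J <- basisGram(smoothed@basis)
  normsq <- rowSums((smoothed@coef %*% J) * smoothed@coef)
  resid <- pmax(normsq - D, 0)
  list(F = D / (resid + epsilon), D = D, resid = resid)
}
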