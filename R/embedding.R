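#' Embed cells in FPC space with a pseudo-temporal directional field
#'
#' Each cell's coordinates are the least-squares solution of
#' \eqn{\Xi\, e_j \approx y_j}: the Moore-Penrose pseudo-inverse of the gene
#' x L score matrix applied to the cell's centered log-expression column.
#' For noiseless rank-L data \eqn{Y = \Xi\, \Phi(t)}, the embedding of cell
#' j recovers \eqn{(\Phi_1(t_j), \dots, \Phi_L(t_j))} exactly. When
#' pseudotime is supplied, the directional field attaches to each cell the
#' eigenfunction derivative vector \eqn{(\Phi_1'(t_j), \dots,
#' \Phi_L'(t_j))}, indicating the local direction of pseudo-temporal
#' progression in FPC coordinates.
#'
#' @param y genes x cells centered log-expression matrix (the same gene set
#'   the scores were computed from).
#' @param xi genes x L FPC score matrix.
#' @param eig the [EigenSystem-class] behind the scores (needed for the
#'   derivative field).
#' @param t optional per-cell pseudotime on \[0, 1\] for the field.
#' @return list with `embedding` (cells x L) and, when `t` is given,
#'   `field` (cells x L derivative vectors).
#' @export
cellEmbedding <- function(y, xi, eig = NULL, t = NULL) {
  y <- as.matrix(y)
  xi <- as.matrix(xi)
  if (nrow(y) != nrow(xi))
    stop("scores must come from the same gene set as the expression rows")
  sv <- svd(xi)
  tol <- max(dim(xi)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(xi))
    warning("rank-deficient score matrix; returning the minimum-norm ",
            "least-squares embedding")
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  emb <- t(pinv %*% y)
  colnames(emb) <- colnames(xi)
  rownames(emb) <- colnames(y)
  out <- list(embedding = emb)
  if (!is.null(t)) {
    if (is.null(eig))
      stop("an eigensystem is required to evaluate the derivative field")
    field <- evalEigenfunctions(eig, .rescalePseudotime(t), deriv = 1L)
    colnames(field) <- colnames(xi)[seq_len(ncol(field))]
    out$field <- field
  }
  out
}
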