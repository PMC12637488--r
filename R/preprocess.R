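#' Log-transform and center an expression matrix
#'
#' Applies `log(x + pseudoCount)` to raw counts (or leaves pre-logged values
#' untouched) and centers every gene at mean zero across cells, recording the
#' removed means so trajectories can be reconstructed on the original scale.
#' Genes constant across all cells become all-zero rows and are flagged so
#' downstream reports can exclude them; they are otherwise carried through
#' (they receive zero scores and p-values of 1).
#'
#' @param x genes x cells numeric matrix.
#' @param scale `"counts"` (log-transform then center) or `"log"` (center
#'   only).
#' @param pseudoCount added inside the log when `scale = "counts"`.
#' @return list with `mat` (centered log matrix), `geneMeans`, and logical
#'   `constant` flags.
#' @examples
#' lc <- logCenterExpression(rbind(g1 = c(0, exp(1) - 1, exp(2) - 1)))
#' lc$mat  # -1 0 1
#' @export
logCenterExpression <- function(x, scale = c("counts", "log"),
                                pseudoCount = 1) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  if (scale == "counts") {
    if (any(x < 0))
      stop("negative values are not valid counts; use scale = \"log\" for ",
           "pre-transformed data")
    x <- log(x + pseudoCount)
  }
  geneMeans <- rowMeans(x)
  mat <- x - geneMeans
  constant <- apply(x, 1L, function(r) max(r) - min(r) == 0)
  list(mat = mat, geneMeans = geneMeans, constant = constant)
}

# Affine rescale of pseudotime to [0, 1]; errors on a degenerate axis.
.rescalePseudotime <- function(t) {
  if (any(!is.finite(t)))
    stop("pseudotime values must be finite")
  r <- range(t)
  if (r[1] == r[2]) {
    if (length(t) > 1L)
      stop("all pseudotime values are identical; a trajectory needs spread")
    return(0)
  }
  (t - r[1]) / (r[2] - r[1])
}
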