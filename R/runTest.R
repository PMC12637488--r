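#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
NULL

# Resolve (expression matrix, pseudotime vector) from the accepted inputs.
.resolveInput <- function(x, pseudotime) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(pseudotime)) {
      if (!"pseudotime" %in% colnames(colData(x)))
        stop("no 'pseudotime' column in colData(x) and none supplied")
      pseudotime <- colData(x)$pseudotime
    }
    nm <- if ("counts" %in% assayNames(x)) "counts" else 1L
    x <- as.matrix(assay(x, nm))
  }
  x <- as.matrix(x)
  if (is.data.frame(pseudotime)) {
    if (!all(c("cell_id", "pseudotime") %in% colnames(pseudotime)))
      stop("pseudotime table needs 'cell_id' and 'pseudotime' columns")
    if (is.null(colnames(x)))
      stop("expression matrix needs cell names to match a pseudotime table")
    idx <- match(colnames(x), pseudotime$cell_id)
    dropped <- sum(is.na(idx))
    if (dropped == ncol(x))
      stop("no overlap between expression cells and pseudotime cell ids")
    if (dropped > 0) {
      warning(dropped, " cell(s) without pseudotime dropped")
      x <- x[, !is.na(idx), drop = FALSE]
      idx <- idx[!is.na(idx)]
    }
    pseudotime <- pseudotime$pseudotime[idx]
  }
  pseudotime <- as.numeric(pseudotime)
  if (length(pseudotime) != ncol(x))
    stop("need one pseudotime value per cell")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("gene", seq_len(nrow(x)))
  list(x = x, t = pseudotime)
}

#' Trajectory differential-expression test in FPC space
#'
#' Runs the full two-stage workflow: log-transform and center expression,
#' smooth every gene against pseudotime with a shared penalized B-spline
#' smoother, eigendecompose the across-gene covariance operator, rank genes
#' by the squared norm of their FPC scores, refine the eigenbasis on the top
#' `tigFraction` of trajectory-informative genes (TIGs), re-project all
#' genes, and calibrate the refined statistics against a pooled permutation
#' null in which pseudotime labels are shuffled across cells while the
#' eigenbasis stays fixed.
#'
#' @param x genes x cells matrix of raw counts (or log expression, see
#'   `scale`), or a `SummarizedExperiment`/`SingleCellExperiment` whose
#'   `counts` assay is used and whose `colData$pseudotime` supplies the axis.
#' @param pseudotime numeric vector (one value per cell, any scale; rescaled
#'   to \[0, 1\]) or a data.frame with `cell_id` and `pseudotime` columns
#'   matched against `colnames(x)`.
#' @param scale `"counts"` (default; log(x + `pseudoCount`) applied) or
#'   `"log"` for pre-transformed input.
#' @param pseudoCount pseudo-count inside the log transform.
#' @param basis an [FpcBasis-class]; default 10 cubic B-splines with the
#'   penalty weight chosen by pooled GCV.
#' @param L fixed number of components; `NULL` (default) retains the
#'   smallest L reaching `varThreshold` cumulative variance, capped at
#'   `maxL`.
#' @param varThreshold,maxL component-selection rule parameters.
#' @param tigFraction fraction of genes kept as TIGs for basis refinement.
#' @param nStages total estimation stages; 2 (default) = one TIG refinement,
#'   1 = no refinement.
#' @param permutations number of pseudotime permutations B.
#' @param alpha significance level for TDEG calls.
#' @param useFdr call TDEGs on BH-FDR q-values (default) or on raw p-values.
#' @param pooled pool permutation statistics across genes (the printed
#'   definition of the empirical p-value) or compare per gene.
#' @param addPseudoCount strictly positive p-values via (1 + count)/(1 + N).
#' @param refitBasis re-estimate the eigensystem inside every permutation
#'   instead of holding it fixed (slow; for sensitivity analysis).
#' @param baseline also compute the functional F baseline statistic and its
#'   pooled permutation p-values (columns `F_stat`, `p_fpcf`).
#' @param epsilon denominator floor for the F baseline.
#' @param seed RNG seed controlling the permutations.
#' @param verbose print stage-level progress.
#' @return A [TrajFpcResult-class]; see [resultTable()].
#' @examples
#' sim <- simulateTrajectoryData(trajSimConfig(
#'   nGenes = 60, nTdeg = 12, nCells = 80, seed = 1))
#' res <- runTrajFpcTest(sim, permutations = 20, seed = 1)
#' head(resultTable(res))
#' @export
runTrajFpcTest <- function(x, pseudotime = NULL,
                           scale = c("counts", "log"), pseudoCount = 1,
                           basis = fpcBasis(), L = NULL, varThreshold = 0.9,
                           maxL = 10L, tigFraction = 0.25, nStages = 2L,
                           permutations = 100L, alpha = 0.05, useFdr = TRUE,
                           pooled = TRUE, addPseudoCount = FALSE,
                           refitBasis = FALSE, baseline = FALSE,
                           epsilon = 1e-8, seed = NULL, verbose = FALSE) {
  scale <- match.arg(scale)
  inp <- .resolveInput(x, pseudotime)
  lc <- logCenterExpression(inp$x, scale = scale, pseudoCount = pseudoCount)
  t01 <- .rescalePseudotime(inp$t)

  if (verbose) message("smoothing ", nrow(lc$mat), " genes over ",
                       length(t01), " cells")
  st <- smoothTrajectories(lc$mat, t01, basis, geneMeans = lc$geneMeans,
                           constant = lc$constant)

  eig <- eigenDecompose(covarianceSurface(st), L = L,
                        varThreshold = varThreshold, maxL = maxL)
  xi <- projectScores(st, eig)
  D <- distanceStatistic(xi)
  stage1 <- list(D = D, eigenvalues = eig@values,
                 varExplained = eig@varExplained)
  if (verbose) message("stage 1: L = ", nComponents(eig), " (",
                       sprintf("%.1f%%", 100 * utils::tail(eig@varExplained, 1)),
                       " variance)")

  tigs <- integer(0)
  if (nStages >= 2L) {
    for (stage in seq_len(nStages - 1L)) {
      tigs <- selectTigs(D, tigFraction)
      eig <- eigenDecompose(covarianceSurface(st, tigs), L = L,
                            varThreshold = varThreshold, maxL = maxL)
      xi <- projectScores(st, eig)
      D <- distanceStatistic(xi)
      if (verbose) message("stage ", stage + 1L, ": ", length(tigs),
                           " TIGs, L = ", nComponents(eig))
    }
  }

  if (verbose) message("permutation null: B = ", permutations)
  null <- permutationNull(lc$mat, st, eig, B = permutations, seed = seed,
                          withResid = baseline, refitBasis = refitBasis,
                          tigs = if (length(tigs)) tigs else NULL)
  p <- empiricalPvalue(D, null, pooled = pooled,
                       addPseudoCount = addPseudoCount)
  q <- p.adjust(p, method = "BH")

  tab <- data.frame(
    gene_id = rownames(lc$mat),
    D = D,
    p = p,
    q = q,
    is_tig = seq_len(nrow(lc$mat)) %in% tigs,
    is_tdeg = if (useFdr) q < alpha else p < alpha,
    constant = lc$constant,
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  if (baseline) {
    fb <- fpcFStatistic(st, eig, xi = xi, epsilon = epsilon)
    Fnull <- null@stats / (null@resid + epsilon)
    tab$F_stat <- fb$F
    tab$p_fpcf <- empiricalPvalue(fb$F, Fnull, pooled = pooled,
                                  addPseudoCount = addPseudoCount)
  }

  new("TrajFpcResult",
      table = tab,
      eigenSystem = eig,
      scores = xi,
      stage1 = stage1,
      config = list(
        scale = scale, pseudoCount = pseudoCount,
        nbasis = basis@nbasis, order = basis@order,
        penaltyOrder = basis@penaltyOrder,
        lambda = st@basis@lambda, L = nComponents(eig),
        varThreshold = varThreshold, maxL = maxL,
        tigFraction = tigFraction, nStages = nStages,
        permutations = as.integer(permutations), alpha = alpha,
        useFdr = useFdr, pooled = pooled,
        addPseudoCount = addPseudoCount, refitBasis = refitBasis,
        baseline = baseline, epsilon = epsilon,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        version = as.character(utils::packageVersion("trajFPC"))
      ))
}

#' @rdname TrajFpcResult-class
#' @param x,object a `TrajFpcResult`.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname TrajFpcResult-class
#' @export
setMethod("resultTable", "TrajFpcResult", function(x) x@table)

#' @rdname TrajFpcResult-class
#' @export
setGeneric("tdegs", function(x) standardGeneric("tdegs"))

#' @rdname TrajFpcResult-class
#' @export
setMethod("tdegs", "TrajFpcResult", function(x)
  x@table$gene_id[x@table$is_tdeg])

#' @rdname TrajFpcResult-class
#' @export
setGeneric("fpcScores", function(x) standardGeneric("fpcScores"))

#' @rdname TrajFpcResult-class
#' @export
setMethod("fpcScores", "TrajFpcResult", function(x) x@scores)

#' @rdname TrajFpcResult-class
#' @export
setGeneric("eigenSystem", function(x) standardGeneric("eigenSystem"))

#' @rdname TrajFpcResult-class
#' @export
setMethod("eigenSystem", "TrajFpcResult", function(x) x@eigenSystem)

#' @rdname TrajFpcResult-class
#' @export
setMethod("show", "TrajFpcResult", function(object) {
  tab <- object@table
  cat("TrajFpcResult:", nrow(tab), "genes\n")
  cat("  components retained:", object@config$L, "| lambda =",
      format(object@config$lambda), "| B =", object@config$permutations,
      "\n")
  cat("  TIGs:", sum(tab$is_tig), "| TDEGs (",
      if (object@config$useFdr) "q" else "p", "<", object@config$alpha,
      "):", sum(tab$is_tdeg), "\n")
})
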