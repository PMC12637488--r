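#' Observed type-I error and power over a significance grid
#'
#' tier(alpha) is the fraction of null genes with p < alpha; power(alpha)
#' the fraction of true TDEGs with p < alpha. Raw p-values and nominal
#' alpha are used (not FDR-adjusted q-values), since calibration at the
#' nominal level is the quantity of interest.
#'
#' @param p per-gene p-values.
#' @param truth logical, `TRUE` for true TDEGs.
#' @param alphaGrid nominal levels.
#' @return data.frame with columns `alpha`, `tier`, `power` (`NA` when a
#'   class is absent).
#' @export
typeIErrorPower <- function(p, truth, alphaGrid = c(0.01, 0.05, 0.1)) {
  if (length(p) != length(truth))
    stop("'p' and 'truth' lengths differ")
  truth <- as.logical(truth)
  data.frame(
    alpha = alphaGrid,
    tier = vapply(alphaGrid, function(a)
      if (any(!truth)) mean(p[!truth] < a) else NA_real_, numeric(1)),
    power = vapply(alphaGrid, function(a)
      if (any(truth)) mean(p[truth] < a) else NA_real_, numeric(1))
  )
}

#' ROC area under the curve from p-value ranking
#'
#' Genes are ranked by ascending p (smaller p = more TDEG-like); ties are
#' handled by midranks, making the result the Mann-Whitney probability that
#' a random true TDEG receives a smaller p than a random null gene. AUC is
#' therefore invariant under any strictly monotone transform of p.
#'
#' @param p per-gene p-values (or any monotone score, small = positive).
#' @param truth logical TDEG labels.
#' @return AUC in \[0, 1\], or `NA` if a class is missing.
#' @export
rocAuc <- function(p, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)                          # midranks
  # U counts (null p > tdeg p) pairs, ties as 1/2
  u <- sum(r[truth]) - n1 * (n1 + 1) / 2
  1 - u / (n1 * n0)
}

#' Benchmark a trajectory DE method on simulated data
#'
#' Simulates `nReplicates` datasets, hands each method the counts and the
#' oracle pseudotime (the true simulated grid, isolating test performance
#' from trajectory-estimation error), and aggregates type-I error, power,
#' ROC-AUC and the false-positive count at alpha = 0.05. A method is any
#' function `(counts, t) -> p` returning one p-value per gene; see
#' [trajFpcMethod()] and [fpcFMethod()] for ready-made wrappers. Replicates
#' on which the method errors are excluded with a warning.
#'
#' @param method callable `(counts, t)` returning per-gene p-values.
#' @param config a [trajSimConfig()]; its seed field is ignored in favor of
#'   per-replicate seeds derived from `seed`.
#' @param nReplicates number of simulated datasets.
#' @param alphaGrid nominal levels for tier/power.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return A [TrajBenchmark-class]; see [benchmarkSummary()].
#' @export
runTrajBenchmark <- function(method, config = trajSimConfig(),
                             nReplicates = 10L,
                             alphaGrid = c(0.01, 0.05, 0.1), seed = 1L) {
  nR <- as.integer(nReplicates)
  tier <- matrix(NA_real_, nR, length(alphaGrid))
  power <- matrix(NA_real_, nR, length(alphaGrid))
  auc <- rep(NA_real_, nR)
  fp <- rep(NA_real_, nR)
  failed <- 0L
  truthCounts <- c(config$nGenes - config$nTdeg, config$nTdeg)

  for (r in seq_len(nR)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulateTrajectoryData(cfg)
    counts <- as.matrix(SummarizedExperiment::assay(sim, "counts"))
    t <- colData(sim)$pseudotime
    truth <- SummarizedExperiment::rowData(sim)$isTDEG
    p <- tryCatch(method(counts, t), error = function(e) {
      warning("method failed on replicate ", r, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(p)) {
      failed <- failed + 1L
      next
    }
    tp <- typeIErrorPower(p, truth, alphaGrid)
    tier[r, ] <- tp$tier
    power[r, ] <- tp$power
    auc[r] <- rocAuc(p, truth)
    fp[r] <- sum(p[!truth] < 0.05)
  }
  new("TrajBenchmark", alphaGrid = alphaGrid, tier = tier, power = power,
      auc = auc, fpCount = fp, nNull = truthCounts[1L],
      nSignal = truthCounts[2L], failed = failed)
}

#' Ready-made benchmark methods
#'
#' `trajFpcMethod()` wraps [runTrajFpcTest()] (raw pooled-permutation
#' p-values); `fpcFMethod()` runs the same pipeline but returns the
#' functional F baseline p-values computed from the identical permutations.
#'
#' @param ... passed on to [runTrajFpcTest()] (e.g. `permutations`, `seed`,
#'   `tigFraction`).
#' @return a function `(counts, t) -> p` for [runTrajBenchmark()].
#' @rdname benchmarkMethods
#' @export
trajFpcMethod <- function(...) {
  function(counts, t) {
    res <- runTrajFpcTest(counts, t, ...)
    resultTable(res)$p
  }
}

#' @rdname benchmarkMethods
#' @export
fpcFMethod <- function(...) {
  function(counts, t) {
    res <- runTrajFpcTest(counts, t, baseline = TRUE, ...)
    resultTable(res)$p_fpcf
  }
}

#' Summarize a benchmark report
#'
#' @param x a [TrajBenchmark-class].
#' @return data.frame of per-alpha mean tier/power with Monte-Carlo standard
#'   errors, plus AUC and false-positive rows.
#' @export
benchmarkSummary <- function(x) {
  stopifnot(is(x, "TrajBenchmark"))
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  }
  out <- data.frame(
    metric = c(paste0("tier@", x@alphaGrid), paste0("power@", x@alphaGrid),
               "auc", "fp@0.05"),
    mean = c(colMeans(x@tier, na.rm = TRUE), colMeans(x@power, na.rm = TRUE),
             mean(x@auc, na.rm = TRUE), mean(x@fpCount, na.rm = TRUE)),
    se = c(apply(x@tier, 2L, se), apply(x@power, 2L, se), se(x@auc),
           se(x@fpCount))
  )
  rownames(out) <- NULL
  out
}

#' @rdname TrajBenchmark-class
#' @param object a `TrajBenchmark`.
#' @export
setMethod("show", "TrajBenchmark", function(object) {
  done <- sum(!is.na(object@auc))
  cat("TrajBenchmark:", done, "replicate(s)",
      if (object@failed) paste0("(", object@failed, " failed)") else "",
      "\n")
  s <- benchmarkSummary(object)
  cat(paste0("  ", s$metric, ": ", signif(s$mean, 3),
             ifelse(is.na(s$se), "", paste0(" (se ", signif(s$se, 2), ")")),
             collapse = "\n"), "\n")
})
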