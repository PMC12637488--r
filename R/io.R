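#' Read a genes x cells expression matrix
#'
#' Supports Matrix Market triplet files (with `genes.tsv` / `barcodes.tsv`
#' sidecars next to the `.mtx`) and dense CSV/TSV with gene rows and a
#' header of cell ids. Orientation is genes-as-rows by convention; set
#' `cellsAsRows = TRUE` for transposed dense input. Duplicate gene ids are
#' rejected.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param cellsAsRows transpose dense input.
#' @return numeric matrix with gene rownames and cell colnames.
#' @export
readExpressionMatrix <- function(path, format = NULL, cellsAsRows = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("mtx", "csv", "tsv"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- file.path(dir, "genes.tsv")
    cells <- file.path(dir, "barcodes.tsv")
    if (file.exists(genes)) {
      g <- read.table(genes, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
      if (length(g) != nrow(m))
        stop("genes.tsv has ", length(g), " entries for ", nrow(m), " rows")
      rownames(m) <- g
    }
    if (file.exists(cells)) {
      b <- read.table(cells, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
      if (length(b) != ncol(m))
        stop("barcodes.tsv has ", length(b), " entries for ", ncol(m),
             " columns")
      colnames(m) <- b
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    if (cellsAsRows) m <- t(m)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene ids in ", path)
  m
}

#' Read a per-cell pseudotime table
#'
#' Expects columns `cell_id` and `pseudotime` (extra columns such as
#' `cluster` are kept); pseudotime must be finite and non-degenerate, and is
#' rescaled to \[0, 1\].
#'
#' @param path CSV/TSV path (delimiter inferred from the extension).
#' @return data.frame with `cell_id`, rescaled `pseudotime`, and any extra
#'   columns.
#' @export
readPseudotime <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("cell_id", "pseudotime") %in% colnames(df)))
    stop("pseudotime table needs 'cell_id' and 'pseudotime' columns")
  if (any(!is.finite(df$pseudotime)))
    stop("non-finite pseudotime values in ", path)
  df$pseudotime <- .rescalePseudotime(df$pseudotime)
  df
}

#' Write test results and run metadata
#'
#' Emits `results.tsv` (gene_id, D, p, q, is_tig, is_tdeg, ...) with a
#' deterministic column order and `metadata.json` capturing the full
#' configuration, seed, retained eigenvalues and variance fractions, so a
#' run can be reproduced exactly from its output directory alone.
#'
#' @param result a [TrajFpcResult-class].
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
writeTestResults <- function(result, outdir) {
  stopifnot(is(result, "TrajFpcResult"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(outdir, "results.tsv")
  json <- file.path(outdir, "metadata.json")
  write.table(result@table, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  eig <- result@eigenSystem
  meta <- c(result@config,
            list(eigenvalues = eig@values,
                 varExplained = eig@varExplained,
                 totalVariance = eig@totalVariance,
                 knots = eig@basis@knots,
                 nTdeg = sum(result@table$is_tdeg),
                 nTig = sum(result@table$is_tig)))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(results = tsv, metadata = json))
}

#' Export an eigensystem
#'
#' Basis coefficients as TSV (one column per eigenfunction) plus a JSON
#' sidecar with knots, order, eigenvalues and variance fractions.
#'
#' @param eig an [EigenSystem-class].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return invisibly, the paths written.
#' @export
exportEigenSystem <- function(eig, prefix) {
  stopifnot(is(eig, "EigenSystem"))
  coef <- eig@coefmat
  colnames(coef) <- paste0("FPC", seq_len(ncol(coef)))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  write.table(coef, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(nbasis = eig@basis@nbasis, order = eig@basis@order,
         knots = eig@basis@knots, penaltyOrder = eig@basis@penaltyOrder,
         lambda = eig@basis@lambda, eigenvalues = eig@values,
         varExplained = eig@varExplained,
         totalVariance = eig@totalVariance),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(coefficients = tsv, metadata = json))
}

#' Write a simulated dataset to plain-text files
#'
#' Counts go to Matrix Market (`counts.mtx` with `genes.tsv`/`barcodes.tsv`
#' sidecars) or dense CSV; the pseudotime grid and ground-truth labels to
#' `pseudotime.tsv` / `truth.tsv`; the configuration to `config.json`.
#'
#' @param sim a `SingleCellExperiment` from [simulateTrajectoryData()].
#' @param outdir output directory.
#' @param format `"mtx"` (default) or `"csv"`.
#' @return invisibly, the output directory.
#' @export
writeSimulatedData <- function(sim, outdir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sim, "counts")
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    file.path(outdir, "counts.mtx"))
    writeLines(rownames(counts), file.path(outdir, "genes.tsv"))
    writeLines(colnames(counts), file.path(outdir, "barcodes.tsv"))
  } else {
    write.csv(counts, file.path(outdir, "counts.csv"), quote = FALSE)
  }
  write.table(
    data.frame(cell_id = colnames(counts),
               pseudotime = colData(sim)$pseudotime),
    file.path(outdir, "pseudotime.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(
    data.frame(gene_id = rownames(counts),
               is_tdeg = SummarizedExperiment::rowData(sim)$isTDEG),
    file.path(outdir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- S4Vectors::metadata(sim)$config
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Round-trip run configuration
#'
#' A flat key-value JSON mirror of every tuning parameter accepted by
#' [runTrajFpcTest()]; values loaded from disk can be spliced into a call
#' with `do.call`.
#'
#' @param config named list of parameters.
#' @param path JSON file path.
#' @return `writeRunConfig` the path invisibly; `readRunConfig` the list.
#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
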