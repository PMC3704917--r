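## TSV input/output for the core containers. All tables are dense TSV with
## header rows of cell or fraction names; sort matrices carry a YAML
## sidecar with per-fraction reporter/polarity metadata.

.writeTSV <- function(df, path, rowLabel) {
  df <- cbind(stats::setNames(data.frame(rownames(df),
                                         stringsAsFactors = FALSE),
                              rowLabel), as.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.readTSVMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read an expression matrix as TSV
#'
#' Genes x cells values; for on/off designs the truth masks are written to a
#' companion \code{<path>.truth} file of 0/1.
#'
#' @param X an [ExpressionMatrix-class].
#' @param path output TSV path.
#' @return (read) an [ExpressionMatrix-class].
#' @export
writeExpressionTSV <- function(X, path) {
  .writeTSV(exprValues(X), path, "gene")
  if (!is.null(truthMask(X)))
    .writeTSV(truthMask(X) * 1L, paste0(path, ".truth"), "gene")
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
  X <- .readTSVMatrix(path)
  tm <- NULL
  if (file.exists(paste0(path, ".truth")))
    tm <- .readTSVMatrix(paste0(path, ".truth")) > 0
  new("ExpressionMatrix", X = X, truthMask = tm)
}

#' Write / read a sort matrix as TSV plus YAML sidecar
#'
#' @param A a [SortMatrix-class].
#' @param path output TSV path; metadata goes to \code{<path>.yaml}.
#' @return (read) a [SortMatrix-class].
#' @export
writeSortMatrixTSV <- function(A, path) {
  .writeTSV(sortValues(A), path, "fraction")
  yaml::write_yaml(lapply(seq_len(nrow(fractionInfo(A))), function(i)
    as.list(fractionInfo(A)[i, ])), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeSortMatrixTSV
#' @export
readSortMatrixTSV <- function(path) {
  A <- .readTSVMatrix(path)
  side <- paste0(path, ".yaml")
  fi <- if (file.exists(side)) {
    do.call(rbind, lapply(yaml::read_yaml(side), function(x)
      data.frame(fraction = as.character(x$fraction),
                 reporter = if (is.null(x$reporter)) NA_character_ else
                   as.character(x$reporter),
                 polarity = as.character(x$polarity),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(fraction = rownames(A), reporter = NA_character_,
               polarity = ifelse(apply(A, 1, function(r)
                 all(abs(r - 1) < 1e-12)), "all", "positive"),
               stringsAsFactors = FALSE)
  }
  new("SortMatrix", A = A, fractionInfo = fi)
}

#' Write a lineage tree (and symmetry map) as TSV
#'
#' @param tree a [LineageTree-class].
#' @param path output TSV path.
#' @param sym optional [SymmetryMap-class], written to \code{symPath}.
#' @param symPath output path for the symmetry table.
#' @export
writeLineageTSV <- function(tree, path, sym = NULL, symPath = NULL) {
  df <- cellTable(tree)
  df$terminal <- as.integer(df$terminal)
  df$parent[is.na(df$parent)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sym)) {
    if (is.null(symPath)) symPath <- paste0(path, ".symmetry")
    utils::write.table(symmetryPairs(sym), symPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write fraction measurements as TSV
#'
#' @param b a [FractionMeasurements-class].
#' @param path output TSV path.
#' @export
writeMeasurementsTSV <- function(b, path) {
  .writeTSV(measurementValues(b), path, "gene")
  invisible(path)
}

#' @rdname writeMeasurementsTSV
#' @export
readMeasurementsTSV <- function(path) {
  new("FractionMeasurements", b = .readTSVMatrix(path))
}

#' Write posterior summaries (EP or sampling) as TSV
#'
#' One row per cell with posterior mean and standard deviation; for an
#' [EPResult-class] the full covariance can be written separately.
#'
#' @param result an [EPResult-class] or [SampleSummary-class].
#' @param path output TSV path.
#' @param covPath optional path for the dense covariance matrix (EP only).
#' @export
writePosteriorTSV <- function(result, path, covPath = NULL) {
  df <- data.frame(cell = names(posteriorMean(result)),
                   mean = unname(posteriorMean(result)),
                   sd = unname(posteriorSd(result)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(covPath) && is(result, "EPResult"))
    .writeTSV(posteriorCov(result), covPath, "cell")
  invisible(path)
}
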