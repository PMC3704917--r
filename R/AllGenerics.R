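#' Number of cells
#'
#' @param x a LineageTree, SortMatrix or ExpressionMatrix.
#' @return integer cell count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Cell names in canonical lineage order
#'
#' @param x a LineageTree, SortMatrix or ExpressionMatrix.
#' @return character vector of cell names.
#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))

#' @rdname nCells
#' @export
setMethod("nCells", "LineageTree", function(x) nrow(x@cells))
#' @rdname nCells
#' @export
setMethod("nCells", "SortMatrix", function(x) ncol(x@A))
#' @rdname nCells
#' @export
setMethod("nCells", "ExpressionMatrix", function(x) ncol(x@X))

#' @rdname cellNames
#' @export
setMethod("cellNames", "LineageTree", function(x) x@cells$cell)
#' @rdname cellNames
#' @export
setMethod("cellNames", "SortMatrix", function(x) colnames(x@A))
#' @rdname cellNames
#' @export
setMethod("cellNames", "ExpressionMatrix", function(x) colnames(x@X))

#' Accessors for the core containers
#'
#' Plain accessor functions returning the underlying base-R objects:
#' \code{sortValues} the fractions x cells matrix, \code{fractionInfo} its
#' per-fraction metadata, \code{exprValues} the genes x cells expression
#' matrix, \code{truthMask} the logical on/off generating mask (or NULL),
#' \code{measurementValues} the genes x fractions totals, \code{estimate}
#' the point estimate of a DeconvResult, \code{posteriorMean} /
#' \code{posteriorSd} / \code{posteriorCov} the moments of an EPResult or
#' SampleSummary.
#'
#' @param x the object.
#' @return the underlying vector, matrix or data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
sortValues <- function(x) x@A

#' @rdname accessors
#' @export
fractionInfo <- function(x) x@fractionInfo

#' @rdname accessors
#' @export
exprValues <- function(x) x@X

#' @rdname accessors
#' @export
truthMask <- function(x) x@truthMask

#' @rdname accessors
#' @export
measurementValues <- function(x) x@b

#' @rdname accessors
#' @export
estimate <- function(x) x@estimate

#' @rdname accessors
#' @export
posteriorMean <- function(x) x@mean

#' @rdname accessors
#' @export
posteriorSd <- function(x) {
  if (is(x, "EPResult")) sqrt(pmax(diag(x@covariance), 0)) else x@sd
}

#' @rdname accessors
#' @export
posteriorCov <- function(x) x@covariance

#' @rdname accessors
#' @export
symmetryPairs <- function(x) x@pairs

#' @rdname accessors
#' @export
cellTable <- function(x) x@cells
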