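#' @import methods
NULL

#' LineageTree: an invariant cell pedigree
#'
#' Represents a rooted cell lineage in which every individual of the organism
#' executes the same pattern of cell divisions, so that a cell's name fully
#' determines its identity. Cells are stored in a canonical depth-first order
#' (children visited in lexicographic name order); that order defines the
#' column index of every sort matrix and expression matrix built on the tree.
#'
#' @slot cells data.frame with columns \code{cell} (character, unique),
#'   \code{parent} (character, \code{NA} for the root) and \code{terminal}
#'   (logical), rows in canonical depth-first order.
#'
#' @seealso [loadLineage()], [generateSyntheticLineage()], [sublineages()]
#' @export
setClass("LineageTree", representation(cells = "data.frame"))

setValidity("LineageTree", function(object) {
  df <- object@cells
  msgs <- character(0)
  if (!all(c("cell", "parent", "terminal") %in% names(df)))
    return("cells must have columns cell, parent, terminal")
  if (nrow(df) == 0L) return("tree has no cells")
  if (anyDuplicated(df$cell))
    msgs <- c(msgs, sprintf("duplicate cell name: '%s'",
                            df$cell[duplicated(df$cell)][1L]))
  roots <- which(is.na(df$parent))
  if (length(roots) != 1L)
    msgs <- c(msgs, sprintf("tree must have exactly one root (found %d)",
                            length(roots)))
  nonroot <- df$parent[!is.na(df$parent)]
  missing <- setdiff(nonroot, df$cell)
  if (length(missing) > 0L)
    msgs <- c(msgs, sprintf("parent '%s' not present in table", missing[1L]))
  # acyclicity: walking parent links from every cell must reach the root
  if (length(msgs) == 0L) {
    pidx <- match(df$parent, df$cell)
    for (i in seq_len(nrow(df))) {
      seen <- logical(nrow(df))
      j <- i
      while (!is.na(pidx[j])) {
        if (seen[j]) return(sprintf("cycle detected involving cell '%s'",
                                    df$cell[i]))
        seen[j] <- TRUE
        j <- pidx[j]
      }
    }
    has_child <- df$cell %in% df$parent
    bad <- !df$terminal & !has_child
    if (any(bad))
      msgs <- c(msgs, sprintf("internal (non-terminal) cell '%s' has no child",
                              df$cell[which(bad)[1L]]))
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' SymmetryMap: left-right symmetric sublineage pairs
#'
#' Lists pairs of sublineage roots occupying mirror-image positions in the
#' body. In many invariant lineages such mirror sublineages typically share
#' expression, so deconvolution benchmarks include patterns that are "on" in
#' both members of a pair.
#'
#' @slot pairs data.frame with character columns \code{left_root} and
#'   \code{right_root}.
#' @export
setClass("SymmetryMap", representation(pairs = "data.frame"))

setValidity("SymmetryMap", function(object) {
  if (!all(c("left_root", "right_root") %in% names(object@pairs)))
    return("pairs must have columns left_root, right_root")
  TRUE
})

#' SortMatrix: fractions-by-cells membership probabilities
#'
#' The sort matrix A has one row per sorted fraction and one column per cell
#' in the lineage; entry \eqn{A_{ij} \in [0,1]} is the probability that cell j
#' ends up in fraction i. Rows come from fluorescent reporters (positive or
#' negative gate) or from an unsorted all-cells sample.
#'
#' @slot A numeric matrix, m fractions x n cells, entries in [0,1]; rownames
#'   are fraction ids, colnames cell names in lineage order.
#' @slot fractionInfo data.frame with columns \code{fraction},
#'   \code{reporter}, \code{polarity} (one of "positive", "negative", "all").
#' @export
setClass("SortMatrix",
         representation(A = "matrix", fractionInfo = "data.frame"))

setValidity("SortMatrix", function(object) {
  A <- object@A
  if (!is.numeric(A)) return("A must be numeric")
  if (any(!is.finite(A))) return("A contains non-finite entries")
  if (any(A < -1e-12) || any(A > 1 + 1e-12))
    return("sort matrix entries must lie in [0, 1]")
  fi <- object@fractionInfo
  if (!all(c("fraction", "reporter", "polarity") %in% names(fi)))
    return("fractionInfo must have columns fraction, reporter, polarity")
  if (nrow(fi) != nrow(A))
    return("fractionInfo rows must match sort-matrix rows")
  if (!all(fi$polarity %in% c("positive", "negative", "all")))
    return("polarity must be positive, negative or all")
  TRUE
})

#' ExpressionMatrix: genes-by-cells non-negative expression
#'
#' Ground-truth or estimated expression, one row per gene and one column per
#' cell in lineage order. For on/off designs the generating truth mask (which
#' cells are "on") is carried alongside the values.
#'
#' @slot X numeric matrix, genes x cells, non-negative.
#' @slot truthMask logical matrix of the same shape for on/off designs, or
#'   NULL for quantitative designs.
#' @export
setClass("ExpressionMatrix",
         representation(X = "matrix", truthMask = "ANY"))

setValidity("ExpressionMatrix", function(object) {
  if (!is.numeric(object@X)) return("X must be numeric")
  if (any(!is.finite(object@X))) return("X contains non-finite values")
  if (any(object@X < 0)) return("expression values must be non-negative")
  tm <- object@truthMask
  if (!is.null(tm)) {
    if (!is.logical(tm) || !identical(dim(tm), dim(object@X)))
      return("truthMask must be a logical matrix matching X")
  }
  TRUE
})

#' FractionMeasurements: genes-by-fractions totals
#'
#' Simulated or observed total expression of each gene in each sorted
#' fraction, i.e. the right-hand sides b of the per-gene systems Ax = b.
#'
#' @slot b numeric matrix, genes x fractions, non-negative; colnames are
#'   fraction ids matching the sort matrix rows.
#' @export
setClass("FractionMeasurements", representation(b = "matrix"))

setValidity("FractionMeasurements", function(object) {
  if (!is.numeric(object@b)) return("b must be numeric")
  if (any(!is.finite(object@b))) return("b contains non-finite values")
  if (any(object@b < -1e-9)) return("fraction totals must be non-negative")
  TRUE
})

#' CorrelationModel: shrunken cell-cell correlation prior
#'
#' A cell-by-cell correlation matrix estimated across genes and shrunk toward
#' the identity, used as the Gaussian prior covariance of the
#' correlation-weighted pseudoinverse.
#'
#' @slot sigma symmetric n x n correlation matrix (unit diagonal).
#' @slot lambda shrinkage intensity in [0, 1].
#' @export
setClass("CorrelationModel",
         representation(sigma = "matrix", lambda = "numeric"))

setValidity("CorrelationModel", function(object) {
  S <- object@sigma
  if (nrow(S) != ncol(S)) return("sigma must be square")
  if (max(abs(S - t(S))) > 1e-8) return("sigma must be symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8)
    return("sigma must have unit diagonal (correlation scale)")
  if (object@lambda < 0 || object@lambda > 1)
    return("lambda must lie in [0, 1]")
  TRUE
})

#' DeconvResult: a point estimate of per-cell expression
#'
#' @slot estimate non-negative n-vector of estimated per-cell expression.
#' @slot method character tag ("naive", "constrained", "correlated").
#' @slot residual Euclidean norm of A %*% estimate - b.
#' @slot feasible TRUE if the equality constraint is met within tolerance.
#' @export
setClass("DeconvResult",
         representation(estimate = "numeric", method = "character",
                        residual = "numeric", feasible = "logical"))

setValidity("DeconvResult", function(object) {
  if (any(object@estimate < -1e-9)) return("estimate must be non-negative")
  if (object@residual < 0) return("residual must be non-negative")
  TRUE
})

#' EPResult: Gaussian posterior approximation from expectation propagation
#'
#' @slot mean posterior mean n-vector (offset already removed).
#' @slot covariance full n x n posterior covariance.
#' @slot converged TRUE if the maximum natural-parameter change fell below
#'   tolerance before the iteration cap.
#' @slot iterations number of parallel sweeps performed.
#' @slot finalStep step size in (0, 1] in effect at the last sweep.
#' @slot offsetRemoved TRUE once the working-scale offset has been
#'   subtracted from the returned mean.
#' @export
setClass("EPResult",
         representation(mean = "numeric", covariance = "matrix",
                        converged = "logical", iterations = "integer",
                        finalStep = "numeric", offsetRemoved = "logical"))

setValidity("EPResult", function(object) {
  if (any(diag(object@covariance) < -1e-8))
    return("marginal variances must be non-negative")
  TRUE
})

#' SampleSummary: hit-and-run posterior sample summary
#'
#' @slot mean,sd per-cell posterior mean and standard deviation.
#' @slot nKept total number of thinned post-burn-in draws across chains.
#' @slot chains optional list of thinned draw matrices (one per chain).
#' @slot omitted logical mask of cells excluded from sampling (fixed at 0).
#' @slot rhat per-cell potential scale reduction (NA for single chains or
#'   omitted cells).
#' @slot pointRegion TRUE if the feasible region is a single point (empty
#'   null space), in which case sd is identically 0.
#' @export
setClass("SampleSummary",
         representation(mean = "numeric", sd = "numeric", nKept = "integer",
                        chains = "list", omitted = "logical",
                        rhat = "numeric", pointRegion = "logical"))

setValidity("SampleSummary", function(object) {
  if (any(object@sd < 0)) return("sd must be non-negative")
  if (any(object@mean[object@omitted] != 0) ||
      any(object@sd[object@omitted] != 0))
    return("omitted cells must have mean and sd fixed at 0")
  TRUE
})

setMethod("show", "LineageTree", function(object) {
  df <- object@cells
  cat(sprintf("LineageTree with %d cells (%d terminal), root '%s'\n",
              nrow(df), sum(df$terminal), df$cell[is.na(df$parent)]))
})

setMethod("show", "SymmetryMap", function(object) {
  cat(sprintf("SymmetryMap with %d symmetric sublineage pairs\n",
              nrow(object@pairs)))
})

setMethod("show", "SortMatrix", function(object) {
  tab <- table(object@fractionInfo$polarity)
  cat(sprintf("SortMatrix: %d fractions x %d cells (%s)\n",
              nrow(object@A), ncol(object@A),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells%s\n",
              nrow(object@X), ncol(object@X),
              if (is.null(object@truthMask)) "" else " (with truth masks)"))
})

setMethod("show", "FractionMeasurements", function(object) {
  cat(sprintf("FractionMeasurements: %d genes x %d fractions\n",
              nrow(object@b), ncol(object@b)))
})

setMethod("show", "CorrelationModel", function(object) {
  cat(sprintf("CorrelationModel: %d cells, shrinkage lambda = %g\n",
              nrow(object@sigma), object@lambda))
})

setMethod("show", "DeconvResult", function(object) {
  cat(sprintf("DeconvResult (%s): %d cells, residual %.3g, feasible: %s\n",
              object@method, length(object@estimate), object@residual,
              object@feasible))
})

setMethod("show", "EPResult", function(object) {
  cat(sprintf(
    "EPResult: %d cells, %s after %d sweeps (final step %.3g)\n",
    length(object@mean),
    if (object@converged) "converged" else "NOT converged",
    object@iterations, object@finalStep))
})

setMethod("show", "SampleSummary", function(object) {
  cat(sprintf(
    "SampleSummary: %d cells (%d omitted), %d kept draws%s\n",
    length(object@mean), sum(object@omitted), object@nKept,
    if (object@pointRegion) ", point region" else ""))
})
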