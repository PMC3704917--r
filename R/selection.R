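## Greedy experiment design: order candidate reporters so that early
## fractions maximize deconvolution accuracy.

#' Greedily order candidate reporters by deconvolution accuracy
#'
#' Iteratively chooses, among the remaining candidates, the reporter whose
#' inclusion maximizes the mean Pearson correlation between the evaluation
#' patterns and their deconvolved estimates, given the fractions chosen so
#' far (the all-cells fraction is always present as a baseline). Compressed
#' sensing suggests near-orthogonal reporter sets perform well; the greedy
#' objective selects them automatically. Ties are broken by candidate input
#' order. Undefined correlations (constant predictions) count as 0 in the
#' objective.
#'
#' @param candidates character vector of candidate reporter names (columns
#'   of \code{intensities}).
#' @param intensities cells x reporters intensity matrix.
#' @param tree a [LineageTree-class].
#' @param evalPatterns an [ExpressionMatrix-class] of evaluation genes
#'   (typically one-lineage on/off patterns).
#' @param method deconvolution engine used by the objective (default
#'   "naive", the cheapest).
#' @param k number of reporters to order (default all candidates).
#' @param includeNegative add negative-gate rows per chosen reporter.
#' @param subsample optional integer: evaluate the objective on a fixed
#'   random subset of this many genes (drawn once with \code{seed}).
#' @param model [CorrelationModel-class] if \code{method = "correlated"}.
#' @param epControl arguments for [epDeconvolve()]-based methods.
#' @param seed integer seed (used only for \code{subsample}).
#' @return data.frame with columns \code{step}, \code{reporter},
#'   \code{objective} (the mean Pearson r achieved at that step) and
#'   attribute \code{method}.
#' @export
greedySelect <- function(candidates, intensities, tree, evalPatterns,
                         method = "naive", k = length(candidates),
                         includeNegative = FALSE, subsample = NULL,
                         model = NULL, epControl = list(), seed = 1L) {
  if (length(candidates) == 0L) stop("candidate set is empty")
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  X <- exprValues(evalPatterns)
  if (nrow(X) == 0L) stop("evalPatterns is empty")
  if (!is.null(subsample) && subsample < nrow(X)) {
    set.seed(seed)
    X <- X[sample.int(nrow(X), subsample), , drop = FALSE]
  }
  chosen <- character(0)
  trace <- numeric(0)
  remaining <- candidates
  for (step in seq_len(k)) {
    scores <- vapply(remaining, function(cand) {
      A <- buildSortMatrix(intensities, reporters = c(chosen, cand),
                           includeNegative = includeNegative,
                           includeAll = TRUE, tree = tree)
      b <- measurementValues(simulateMeasurements(A, X))
      est <- exprValues(deconvolveMatrixQuiet(A, b, method, model,
                                              epControl))
      r <- .rowPearson(est, X)
      mean(ifelse(is.finite(r), r, 0))
    }, numeric(1))
    best <- which.max(scores)   # first max wins: input-order tie-break
    chosen <- c(chosen, remaining[best])
    trace <- c(trace, scores[best])
    remaining <- remaining[-best]
  }
  out <- data.frame(step = seq_len(k), reporter = chosen,
                    objective = unname(trace), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

# deconvolveMatrix that tolerates per-gene failures (rows of zeros)
deconvolveMatrixQuiet <- function(A, b, method, model = NULL,
                                  epControl = list()) {
  Am <- .asA(A)
  bm <- if (is(b, "FractionMeasurements")) b@b else as.matrix(b)
  if (method == "naive") {
    # one pseudoinverse serves every gene: x-hat = clamp(A+ b, 0)
    est <- pmax(bm %*% t(.pinv(Am)), 0)
    dimnames(est) <- list(rownames(bm), colnames(Am))
    return(new("ExpressionMatrix", X = est, truthMask = NULL))
  }
  est <- matrix(0, nrow(bm), ncol(Am),
                dimnames = list(rownames(bm), colnames(Am)))
  for (g in seq_len(nrow(bm))) {
    fit <- .deconvOne(method, Am, bm[g, ], model, epControl)
    if (!fit$failed) est[g, ] <- pmax(fit$x, 0)
  }
  new("ExpressionMatrix", X = est, truthMask = NULL)
}
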