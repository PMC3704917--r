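## Synthetic expression generators: lineage on/off patterns (normal or gamma
## noise), correlated multivariate-normal patterns, and the shrunken
## cell-cell correlation model.

#' Truncate negative expression values to zero
#'
#' @param X numeric vector/matrix or [ExpressionMatrix-class].
#' @return same shape with elementwise \code{max(x, 0)}.
#' @export
truncateNegative <- function(X) {
  if (is(X, "ExpressionMatrix"))
    return(new("ExpressionMatrix", X = pmax(X@X, 0), truthMask = X@truthMask))
  pmax(X, 0)
}

#' Shrunken cell-cell correlation model
#'
#' Estimates the correlation between every pair of cells across genes and
#' shrinks it toward the identity: \eqn{\Sigma = (1-\lambda)\hat R + \lambda
#' I}. Shrinkage keeps the matrix well conditioned when genes are fewer than
#' cells; the default intensity is 0.05.
#'
#' @param X an [ExpressionMatrix-class] or genes x cells matrix (>= 2 genes).
#' @param lambda shrinkage intensity in [0, 1].
#' @return a [CorrelationModel-class].
#' @export
shrunkenCorrelation <- function(X, lambda = 0.05) {
  Xmat <- if (is(X, "ExpressionMatrix")) X@X else as.matrix(X)
  if (nrow(Xmat) < 2) stop("need >= 2 genes to estimate correlation")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  sds <- apply(Xmat, 2, stats::sd)
  R <- suppressWarnings(stats::cor(Xmat))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance cell(s); their correlations set to 0",
                    sum(sds == 0)))
  }
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  S <- (1 - lambda) * R + lambda * diag(ncol(Xmat))
  dimnames(S) <- list(colnames(Xmat), colnames(Xmat))
  obj <- new("CorrelationModel", sigma = S, lambda = lambda)
  validObject(obj)
  obj
}

#' Simulate correlated expression patterns
#'
#' Draws gene expression vectors from a multivariate normal distribution with
#' mean 0 and the model's cell-cell covariance, then truncates negative
#' values to zero. Emulates random patterns whose between-cell correlation
#' structure matches that of real reporter expression.
#'
#' @param model a [CorrelationModel-class] (or any PSD covariance matrix).
#' @param nGenes number of synthetic genes (default 200).
#' @param seed integer seed.
#' @return an [ExpressionMatrix-class] without truth masks.
#' @export
simulateCorrelatedPatterns <- function(model, nGenes = 200L, seed = 1L) {
  S <- if (is(model, "CorrelationModel")) model@sigma else as.matrix(model)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf(
      "covariance is not positive semi-definite (min eigenvalue %.3g, max %.3g)",
      min(ev), max(ev)))
  set.seed(seed)
  X <- MASS::mvrnorm(n = nGenes, mu = rep(0, ncol(S)),
                     Sigma = S + 1e-10 * max(ev) * diag(ncol(S)))
  X <- matrix(pmax(X, 0), nrow = nGenes,
              dimnames = list(paste0("corr_gene", seq_len(nGenes)),
                              colnames(S)))
  new("ExpressionMatrix", X = X, truthMask = NULL)
}

#' Simulate lineage-blockwise on/off expression patterns
#'
#' Generates one gene per qualifying sublineage (\code{mode = "one"}) or per
#' left-right symmetric sublineage pair (\code{mode = "two_symmetric"}):
#' cells inside the sublineage are "on" and the rest "off", with values drawn
#' i.i.d. from the configured noise distributions and negatives truncated to
#' zero. Defaults: on ~ N(mean 10, variance 11), off ~ N(mean 0, variance 1);
#' \code{noise = "gamma"} uses Gamma(shape, scale) for on cells and
#' Gamma(1, 1) for off cells. Setting \code{literalParameterization} swaps
#' the normal on/off parameter sets (on ~ N(0,1), off ~ N(10,11)) -- some
#' descriptions of this design transpose the two sets, which makes off
#' cells brighter than on cells; the switch reproduces that variant for
#' comparison.
#'
#' @param tree a [LineageTree-class].
#' @param sym a [SymmetryMap-class] (required for
#'   \code{mode = "two_symmetric"}).
#' @param mode "one" or "two_symmetric".
#' @param minCells minimum sublineage size (default 5; both sides must
#'   qualify in pair mode).
#' @param noise "normal" or "gamma".
#' @param params list of distribution parameters: for normal noise
#'   \code{onMean}, \code{onVar}, \code{offMean}, \code{offVar}; for gamma
#'   noise \code{onShape}, \code{onScale}, \code{offShape}, \code{offScale}.
#' @param seed integer seed.
#' @param count sublineage-size counting convention, see [sublineages()].
#' @param literalParameterization logical; see Details.
#' @return an [ExpressionMatrix-class] with truth masks (genes named after
#'   the sublineage root or pair).
#' @export
simulateLineagePatterns <- function(tree, sym = NULL,
                                    mode = c("one", "two_symmetric"),
                                    minCells = 5L,
                                    noise = c("normal", "gamma"),
                                    params = list(), seed = 1L,
                                    count = c("all", "terminal"),
                                    literalParameterization = FALSE) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  count <- match.arg(count)
  masks <- if (mode == "one") {
    sublineages(tree, minCells = minCells, count = count)
  } else {
    if (is.null(sym)) stop("mode 'two_symmetric' requires a SymmetryMap")
    symmetricPairSublineages(tree, sym, minCells = minCells, count = count)
  }
  n <- nCells(tree)
  if (length(masks) == 0L) {
    warning("no qualifying sublineages; returning an empty matrix")
    X <- matrix(numeric(0), nrow = 0, ncol = n,
                dimnames = list(NULL, cellNames(tree)))
    return(new("ExpressionMatrix", X = X,
               truthMask = matrix(logical(0), nrow = 0, ncol = n,
                                  dimnames = list(NULL, cellNames(tree)))))
  }
  defaults <- list(onMean = 10, onVar = 11, offMean = 0, offVar = 1,
                   onShape = 10, onScale = 1, offShape = 1, offScale = 1)
  p <- utils::modifyList(defaults, params)
  if (literalParameterization && noise == "normal") {
    p[c("onMean", "onVar", "offMean", "offVar")] <-
      p[c("offMean", "offVar", "onMean", "onVar")]
  }
  set.seed(seed)
  X <- matrix(0, nrow = length(masks), ncol = n,
              dimnames = list(names(masks), cellNames(tree)))
  TM <- matrix(FALSE, nrow = length(masks), ncol = n,
               dimnames = dimnames(X))
  for (g in seq_along(masks)) {
    on <- masks[[g]]
    if (noise == "normal") {
      X[g, on] <- stats::rnorm(sum(on), p$onMean, sqrt(p$onVar))
      X[g, !on] <- stats::rnorm(sum(!on), p$offMean, sqrt(p$offVar))
    } else {
      X[g, on] <- stats::rgamma(sum(on), shape = p$onShape,
                                scale = p$onScale)
      X[g, !on] <- stats::rgamma(sum(!on), shape = p$offShape,
                                 scale = p$offScale)
    }
    TM[g, ] <- on
  }
  new("ExpressionMatrix", X = pmax(X, 0), truthMask = TM)
}
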