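## Pseudoinverse-family point estimators for x in Ax = b, x >= 0.

# Moore-Penrose pseudoinverse via SVD, relative cutoff 1e-10 * sigma_max
.pinv <- function(A, rtol = 1e-10) {
  A <- as.matrix(A)
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# orthonormal basis of the null space of A (n x k), possibly 0 columns
.nullBasis <- function(A, rtol = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  sv <- svd(A, nu = 0, nv = n)
  rank <- sum(sv$d > rtol * max(sv$d, 0))
  if (rank >= n) return(matrix(0, n, 0))
  sv$v[, (rank + 1):n, drop = FALSE]
}

# Least Distance Programming: min ||x|| s.t. G x >= h  (Lawson-Hanson ch.23)
# returns list(x, feasible)
.ldp <- function(G, h) {
  n <- ncol(G)
  if (nrow(G) == 0L) return(list(x = numeric(n), feasible = TRUE))
  if (all(h <= 1e-12)) return(list(x = numeric(n), feasible = TRUE))
  E <- rbind(t(G), as.numeric(h))
  f <- c(numeric(n), 1)
  fit <- pracma::lsqnonneg(E, f)
  r <- as.numeric(E %*% fit$x - f)
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) return(list(x = numeric(n), feasible = FALSE))
  list(x = -r[seq_len(n)] / r[n + 1L], feasible = TRUE)
}

.asA <- function(A) if (is(A, "SortMatrix")) A@A else as.matrix(A)

.mkResult <- function(x, A, b, method, tol = 1e-6) {
  x <- pmax(as.numeric(x), 0)
  res <- sqrt(sum((A %*% x - b)^2))
  new("DeconvResult", estimate = x, method = method, residual = res,
      feasible = res <= tol * sqrt(sum(b^2)) + 1e-12)
}

#' Naive pseudoinverse deconvolution
#'
#' Computes the minimum-2-norm solution \eqn{A^+ b} of the linear system and
#' truncates negative entries at zero. Truncation will in general violate the
#' equality constraint, which the \code{feasible} flag reports.
#'
#' @param A a [SortMatrix-class] or m x n numeric matrix.
#' @param b numeric m-vector of fraction measurements.
#' @return a [DeconvResult-class].
#' @examples
#' naivePseudoinverse(matrix(c(1, 1), 1), 2)  # -> c(1, 1)
#' @export
naivePseudoinverse <- function(A, b) {
  Am <- .asA(A); b <- as.numeric(b)
  if (length(b) != nrow(Am))
    stop(sprintf("b has %d entries but A has %d rows", length(b), nrow(Am)))
  .mkResult(.pinv(Am) %*% b, Am, b, "naive")
}

# minimum Sigma^-1-norm (or 2-norm when L = I) feasible point of
# {x >= 0 : Ax = b}; returns NULL when that set is (numerically) empty
.minNormFeasible <- function(Am, b, L = NULL) {
  if (is.null(L)) {
    Aw <- Am
    toX <- identity
  } else {
    Aw <- Am %*% L
    toX <- function(y) L %*% y
  }
  yp <- as.numeric(.pinv(Aw) %*% b)
  # b must lie in the range of A for the equality to be satisfiable
  if (sqrt(sum((Aw %*% yp - b)^2)) > 1e-8 * max(1, sqrt(sum(b^2))))
    return(NULL)
  N <- .nullBasis(Aw)
  xp <- as.numeric(toX(yp))
  if (ncol(N) == 0L) {
    if (min(xp) < -1e-8 * max(1, max(abs(xp)))) return(NULL)
    return(pmax(xp, 0))
  }
  G <- if (is.null(L)) N else L %*% N
  sol <- .ldp(G, -xp)
  if (!sol$feasible) return(NULL)
  x <- xp + as.numeric(G %*% sol$x)
  if (min(x) < -1e-6 * max(1, max(abs(x)))) return(NULL)
  pmax(x, 0)
}

#' Constrained pseudoinverse deconvolution
#'
#' Finds the minimum-2-norm point of \eqn{\{x \ge 0 : Ax = b\}}, the maximum
#' likelihood estimate under a standard normal prior on x subject to the
#' measurement and non-negativity constraints. When that set is empty (the
#' equality cannot be met with non-negative expression, e.g. under
#' measurement noise) the estimator falls back to the non-negative
#' least-squares residual minimizer and, among all residual minimizers,
#' returns the minimum-norm one; \code{feasible} is then FALSE.
#'
#' The equality constraint is eliminated through an orthonormal null-space
#' basis of A, reducing the problem to least-distance programming solved by a
#' single non-negative least-squares call.
#'
#' @inheritParams naivePseudoinverse
#' @return a [DeconvResult-class].
#' @export
constrainedPseudoinverse <- function(A, b) {
  Am <- .asA(A); b <- as.numeric(b)
  if (length(b) != nrow(Am))
    stop(sprintf("b has %d entries but A has %d rows", length(b), nrow(Am)))
  x <- .minNormFeasible(Am, b)
  if (is.null(x)) {
    xn <- pracma::lsqnonneg(Am, b)$x
    bh <- as.numeric(Am %*% xn)
    x2 <- .minNormFeasible(Am, bh)
    x <- if (is.null(x2)) xn else x2
  }
  .mkResult(x, Am, b, "constrained")
}

#' Correlation-weighted pseudoinverse deconvolution
#'
#' Maximum-likelihood estimate under a Gaussian prior with cell-cell
#' covariance \eqn{\Sigma}: minimizes \eqn{x^\top \Sigma^{-1} x} subject to
#' \eqn{Ax = b, x \ge 0}. With \eqn{\Sigma = I} this reduces exactly to
#' [constrainedPseudoinverse()]. Uses the Cholesky substitution
#' \eqn{x = L y}, \eqn{\Sigma = L L^\top}, turning the objective into
#' \eqn{\|y\|^2} and the problem into least-distance programming. The same
#' infeasible-equality fallback applies, with the \eqn{\Sigma^{-1}}-weighted
#' objective among residual minimizers.
#'
#' @inheritParams naivePseudoinverse
#' @param model a [CorrelationModel-class] or a positive-definite covariance
#'   matrix.
#' @return a [DeconvResult-class].
#' @export
correlatedPseudoinverse <- function(A, b, model) {
  Am <- .asA(A); b <- as.numeric(b)
  if (length(b) != nrow(Am))
    stop(sprintf("b has %d entries but A has %d rows", length(b), nrow(Am)))
  S <- if (is(model, "CorrelationModel")) model@sigma else as.matrix(model)
  if (ncol(S) != ncol(Am))
    stop("covariance dimension does not match the number of cells")
  U <- tryCatch(chol(S), error = function(e)
    stop("covariance is singular; use shrinkage lambda > 0 ",
         "(shrunkenCorrelation)", call. = FALSE))
  L <- t(U)
  x <- .minNormFeasible(Am, b, L = L)
  if (is.null(x)) {
    xn <- pracma::lsqnonneg(Am, b)$x
    bh <- as.numeric(Am %*% xn)
    x2 <- .minNormFeasible(Am, bh, L = L)
    x <- if (is.null(x2)) xn else x2
  }
  .mkResult(x, Am, b, "correlated")
}

#' Deconvolve every gene of a measurement matrix
#'
#' Convenience wrapper applying one of the point estimators to each row of a
#' [FractionMeasurements-class].
#'
#' @param A a [SortMatrix-class] or numeric matrix.
#' @param b a [FractionMeasurements-class] or genes x fractions matrix.
#' @param method "naive", "constrained" or "correlated".
#' @param model [CorrelationModel-class], required for
#'   \code{method = "correlated"}.
#' @return an [ExpressionMatrix-class] of per-gene estimates.
#' @export
deconvolveMatrix <- function(A, b, method = c("naive", "constrained",
                                              "correlated"), model = NULL) {
  method <- match.arg(method)
  Am <- .asA(A)
  bm <- if (is(b, "FractionMeasurements")) b@b else as.matrix(b)
  est <- t(vapply(seq_len(nrow(bm)), function(g) {
    r <- switch(method,
                naive = naivePseudoinverse(Am, bm[g, ]),
                constrained = constrainedPseudoinverse(Am, bm[g, ]),
                correlated = correlatedPseudoinverse(Am, bm[g, ], model))
    r@estimate
  }, numeric(ncol(Am))))
  dimnames(est) <- list(rownames(bm), colnames(Am))
  new("ExpressionMatrix", X = est, truthMask = NULL)
}
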