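## Random-direction (hit-and-run) MCMC over the feasible polytope, with
## Gelman-Rubin convergence diagnostics.

#' Sample the feasible polytope by hit-and-run MCMC
#'
#' Draws uniform samples from \eqn{\{x \ge 0 : Ax = b\}} by random-direction
#' Markov chain Monte Carlo: each step moves along a uniformly random
#' direction in the null space of A, restricted to the feasible segment.
#' Cells whose constrained-pseudoinverse estimate is (numerically) zero are
#' omitted from sampling and fixed at 0 -- without this restriction the
#' chain cannot move when the region touches many coordinate hyperplanes.
#' Each chain starts from a distinct feasible point obtained by a short
#' seeded pre-walk from \code{x0}.
#'
#' Defaults follow the reference protocol (ten million burn-in and sampling
#' iterations, thinned to every 1000th draw); scale them down for small
#' problems.
#'
#' @param A a [SortMatrix-class] or m x n numeric matrix.
#' @param b numeric m-vector.
#' @param x0 feasible start (default: the [constrainedPseudoinverse()]
#'   estimate). Must satisfy x0 >= 0 and A x0 = b within tolerance.
#' @param nBurn burn-in iterations per chain (default 1e7).
#' @param nIter post-burn-in iterations per chain (default 1e7).
#' @param thin keep every \code{thin}-th draw (default 1000).
#' @param nChains number of independent chains (default 1; >= 2 enables the
#'   potential scale reduction diagnostic).
#' @param seed integer seed; chain c uses \code{seed + c - 1}.
#' @param keepChains retain the thinned draws per chain (default TRUE).
#' @param omitThreshold relative threshold below which a cell's
#'   constrained-pinv estimate counts as zero expression (default 1e-8).
#' @return a [SampleSummary-class].
#' @export
sampleFeasible <- function(A, b, x0 = NULL, nBurn = 1e7, nIter = 1e7,
                           thin = 1000L, nChains = 1L, seed = 1L,
                           keepChains = TRUE, omitThreshold = 1e-8) {
  Am <- .asA(A)
  b <- as.numeric(b)
  n <- ncol(Am)
  if (is.null(x0)) x0 <- constrainedPseudoinverse(Am, b)@estimate
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("x0 length does not match the number of cells")
  if (any(x0 < -1e-9))
    stop("x0 is infeasible: negative entries")
  if (sqrt(sum((Am %*% x0 - b)^2)) > 1e-6 * max(1, sqrt(sum(b^2))))
    stop("x0 is infeasible: A x0 != b beyond tolerance")
  omitted <- x0 < omitThreshold * max(x0, 0)
  if (all(omitted)) omitted[] <- FALSE     # all-zero solution: keep frame
  keep <- which(!omitted)
  Asub <- Am[, keep, drop = FALSE]
  N <- .nullBasis(Asub)
  cn <- colnames(Am)
  if (ncol(N) == 0L) {
    out <- new("SampleSummary", mean = stats::setNames(x0, cn),
               sd = stats::setNames(numeric(n), cn), nKept = 0L,
               chains = list(), omitted = omitted,
               rhat = stats::setNames(rep(NA_real_, n), cn),
               pointRegion = TRUE)
    return(out)
  }
  chains <- vector("list", nChains)
  for (cix in seq_len(nChains)) {
    set.seed(seed + cix - 1L)
    # distinct feasible start: short pre-walk from x0 under the chain's seed
    start <- .hitAndRunChain(x0[keep], N, 0L, 200L, 200L)
    start <- if (nrow(start) > 0L) start[nrow(start), ] else x0[keep]
    draws <- .hitAndRunChain(start, N, as.integer(nBurn), as.integer(nIter),
                             as.integer(thin))
    full <- matrix(0, nrow(draws), n, dimnames = list(NULL, cn))
    full[, keep] <- draws
    chains[[cix]] <- full
  }
  allDraws <- do.call(rbind, chains)
  mu <- colMeans(allDraws)
  sdv <- apply(allDraws, 2, stats::sd)
  mu[omitted] <- 0; sdv[omitted] <- 0
  rhat <- stats::setNames(rep(NA_real_, n), cn)
  if (nChains >= 2L && nrow(chains[[1L]]) >= 2L) {
    rh <- potentialScaleReduction(lapply(chains, function(ch)
      ch[, keep, drop = FALSE]))
    rhat[keep] <- rh
  }
  new("SampleSummary", mean = mu, sd = sdv, nKept = nrow(allDraws),
      chains = if (keepChains) chains else list(), omitted = omitted,
      rhat = rhat, pointRegion = FALSE)
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic between/within-chain variance diagnostic
#' \eqn{\hat R = \sqrt{((n-1)/n\, W + B/n)/W}} computed per coordinate from
#' two or more aligned chains; values near 1 indicate convergence and the
#' usual rule of thumb flags \eqn{\hat R > 1.1}.
#'
#' @param chains list of >= 2 numeric matrices (draws x coordinates) or
#'   vectors, all of equal length >= 2.
#' @return numeric vector of per-coordinate \eqn{\hat R}.
#' @export
potentialScaleReduction <- function(chains) {
  if (length(chains) < 2L) stop("need at least two chains")
  chains <- lapply(chains, function(ch)
    if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch))
  n <- nrow(chains[[1L]])
  if (n < 2L) stop("chains must have length >= 2")
  if (!all(vapply(chains, nrow, 1L) == n))
    stop("chains must have equal length")
  means <- do.call(rbind, lapply(chains, colMeans))
  vars <- do.call(rbind, lapply(chains, function(ch)
    apply(ch, 2, stats::var)))
  W <- colMeans(vars)
  B <- n * apply(means, 2, stats::var)
  varPlus <- (n - 1) / n * W + B / n
  rhat <- sqrt(varPlus / W)
  rhat[W == 0 & B == 0] <- 1
  rhat[W == 0 & B > 0] <- Inf
  unname(rhat)
}
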