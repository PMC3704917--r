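## Expectation propagation over the feasible polytope {x >= 0 : Ax = b}.
##
## One univariate Gaussian site per cell approximates the x_i >= 0
## indicator; sites are refined in parallel sweeps by truncated-normal
## moment matching on the cavity, and the equality constraint Ax = b is
## imposed by exact Gaussian conditioning (with a small jitter) at every
## sweep.

# stable phi(a)/Phi(a)
.millsRatioInv <- function(a) {
  exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
}

#' Expectation-propagation deconvolution
#'
#' Approximates the uniform distribution over the feasible polytope
#' \eqn{\{x \ge 0 : Ax = b\}} with a multivariate normal, giving both a point
#' estimate (the mean) and an intrinsic uncertainty estimate (the
#' covariance). The working scale is relative expression: b is divided by
#' the total expression (the all-cells fraction measurement when present,
#' otherwise \code{sum(b)/rank(A)}), a small offset is added to every cell's
#' relative expression to keep the region strictly interior (and subtracted
#' from the returned mean), and a zero-mean Gaussian prior with variance
#' \code{priorScale} times the total stabilizes the iteration.
#'
#' Sites are updated in parallel from the start-of-sweep posterior, scaled
#' by a step size that starts at 1. In damped mode a numerical failure
#' (negative or collapsed cavity variance, non-finite update) halves the
#' step size and retries from the last valid state, so a result is always
#' returned, with \code{converged} reporting whether the natural parameters
#' stabilized. In undamped mode the same failure raises an error naming the
#' sweep.
#'
#' @param A a [SortMatrix-class] or m x n numeric matrix.
#' @param b numeric m-vector of non-negative fraction measurements.
#' @param priorScale prior variance multiplier (default 100 x total
#'   expression).
#' @param offset working-scale offset added to each cell's relative
#'   expression (default 1e-3).
#' @param damped logical; see Details (default TRUE).
#' @param maxIter maximum number of parallel sweeps (default 200).
#' @param tol convergence tolerance on the maximum natural-parameter change
#'   (default 1e-6).
#' @param seed ignored (the algorithm is deterministic); accepted so that
#'   callers can treat all deconvolution engines uniformly.
#' @return an [EPResult-class] with full covariance.
#' @examples
#' r <- epDeconvolve(matrix(c(1, 1), 1), 1)
#' posteriorMean(r)          # ~ c(0.5, 0.5)
#' posteriorSd(r)            # ~ 0.29 each (uniform on the segment)
#' @export
epDeconvolve <- function(A, b, priorScale = 100, offset = 1e-3,
                         damped = TRUE, maxIter = 200L, tol = 1e-6,
                         seed = NULL) {
  Am <- .asA(A)
  b <- as.numeric(b)
  if (length(b) != nrow(Am))
    stop(sprintf("b has %d entries but A has %d rows", length(b), nrow(Am)))
  if (any(b < -1e-9)) stop("b must be non-negative")
  n <- ncol(Am); m <- nrow(Am)

  # total expression: the all-cells fraction if one exists, else a rank proxy
  allRow <- which(apply(Am, 1, function(r) all(abs(r - 1) < 1e-12)))
  total <- if (length(allRow) > 0L) b[allRow[1L]] else {
    sv <- svd(Am, nu = 0, nv = 0)$d
    sum(b) / max(1, sum(sv > 1e-10 * max(sv)))
  }
  if (total <= 0) total <- 1
  bw <- b / total + offset * as.numeric(Am %*% rep(1, n))

  tauPrior <- 1 / priorScale          # prior precision per cell
  siteTau <- numeric(n)               # site precisions (>= 0)
  siteNu <- numeric(n)                # site precision x mean
  step <- 1
  converged <- FALSE
  it <- 0L

  conditionOn <- function(siteTau, siteNu, full = FALSE) {
    d <- tauPrior + siteTau
    S <- 1 / d
    h <- siteNu * S
    AS <- sweep(Am, 2L, S, "*")              # m x n = A diag(S)
    K <- AS %*% t(Am)
    K <- K + diag(1e-8 * max(mean(diag(K)), 1e-300), m)
    W <- tryCatch(solve(K, AS), error = function(e) NULL)
    if (is.null(W)) return(NULL)
    resid <- bw - as.numeric(Am %*% h)
    mu <- h + as.numeric(t(AS) %*% solve(K, resid))
    if (full) {
      Sig <- diag(S, n) - t(AS) %*% W
      list(mu = mu, Sig = Sig, diagSig = pmax(diag(Sig), 0))
    } else {
      list(mu = mu, diagSig = pmax(S - colSums(AS * W), 0))
    }
  }

  fail <- function(what) {
    if (!damped)
      stop(sprintf("EP diverged numerically at sweep %d (%s); use damped mode",
                   it, what), call. = FALSE)
    NULL
  }

  repeat {
    if (it >= maxIter) break
    it <- it + 1L
    post <- conditionOn(siteTau, siteNu)
    ok <- !is.null(post) && all(is.finite(post$mu)) &&
      all(is.finite(post$diagSig))
    newTau <- siteTau; newNu <- siteNu
    if (ok) {
      sii <- pmax(post$diagSig, 1e-14)
      cPrec <- 1 / sii - siteTau             # cavity precisions
      bad <- !is.finite(cPrec) | cPrec <= 0 | cPrec > 1e12
      if (any(bad)) ok <- FALSE
      if (ok) {
        v <- 1 / cPrec
        mcav <- v * (post$mu / sii - siteNu)
        alpha <- mcav / sqrt(v)
        z <- .millsRatioInv(alpha)
        mstar <- mcav + sqrt(v) * z
        vstar <- pmax(v * (1 - z * (z + alpha)), 1e-14 * v)
        tStar <- 1 / vstar - cPrec
        nStar <- mstar / vstar - mcav * cPrec
        tStar <- pmax(tStar, 0)
        if (any(!is.finite(tStar)) || any(!is.finite(nStar))) {
          ok <- FALSE
        } else {
          newTau <- (1 - step) * siteTau + step * tStar
          newNu <- (1 - step) * siteNu + step * nStar
        }
      }
    }
    if (!ok) {
      fail("cavity or update failure")
      step <- step / 2
      if (step < 2^-20) break
      next
    }
    delta <- max(abs(newTau - siteTau), abs(newNu - siteNu))
    siteTau <- newTau; siteNu <- newNu
    if (is.finite(delta) && delta < tol) { converged <- TRUE; break }
  }

  post <- conditionOn(siteTau, siteNu, full = TRUE)
  if (is.null(post))
    stop("EP failed to produce a posterior (singular conditioning system)")
  mu <- (post$mu - offset) * total
  Sig <- post$Sig * total^2
  Sig <- (Sig + t(Sig)) / 2
  diag(Sig) <- pmax(diag(Sig), 0)
  names(mu) <- colnames(Am)
  dimnames(Sig) <- list(colnames(Am), colnames(Am))
  new("EPResult", mean = mu, covariance = Sig, converged = converged,
      iterations = it, finalStep = step, offsetRemoved = TRUE)
}

#' Group expression summary from an EP posterior
#'
#' Total (or average) expression of a gene over a group of cells, typically a
#' sublineage: the group mean sums the posterior mean over the mask and the
#' group variance is the quadratic form \eqn{1^\top \Sigma_{mask} 1}, so
#' negative covariances narrow the group interval. Group predictions are
#' usually narrower than per-cell ones because they do not commit to which
#' cell inside the group expresses.
#'
#' @param result an [EPResult-class] with full covariance.
#' @param mask logical cell-mask (e.g. from [lineageMask()]).
#' @param statistic "total" or "average".
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
epGroupSummary <- function(result, mask, statistic = c("total", "average")) {
  statistic <- match.arg(statistic)
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask must select at least one cell")
  k <- sum(mask)
  m <- sum(result@mean[mask])
  v <- sum(result@covariance[mask, mask])
  if (statistic == "average") { m <- m / k; v <- v / k^2 }
  c(mean = m, sd = sqrt(max(v, 0)))
}
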