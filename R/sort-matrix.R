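## Sort-matrix construction from reporter intensities and measurement
## simulation b = Ax.

#' Posterior probability that a cell expresses a reporter
#'
#' Converts a background-subtracted fluorescence intensity into the posterior
#' probability that the cell is "on" for the reporter, under a two-component
#' equal-prior Gaussian mixture: off cells have intensity N(mean 0, sd 1000)
#' and on cells N(mean 2000, sd 1000). With equal variances the posterior is
#' logistic in the intensity, with log-odds
#' \eqn{(\mu_1-\mu_0)(x - (\mu_0+\mu_1)/2)/\sigma^2}.
#'
#' @param intensity numeric vector of fluorescence intensities (arbitrary
#'   units; may be negative after background subtraction).
#' @param meanOff,meanOn,sd mixture parameters (defaults 0, 2000, 1000).
#' @return probabilities in (0, 1) (0/1 reached only at saturating
#'   intensities in floating point), strictly increasing in intensity.
#' @examples
#' intensityToOnProbability(c(0, 1000, 2000))
#' @export
intensityToOnProbability <- function(intensity, meanOff = 0, meanOn = 2000,
                                     sd = 1000) {
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  logOdds <- (meanOn - meanOff) * (intensity - (meanOff + meanOn) / 2) / sd^2
  stats::plogis(logOdds)
}

#' Build a sort matrix from per-cell reporter intensities
#'
#' Each requested reporter contributes a positive-gate row of on-probabilities
#' (via [intensityToOnProbability()]); optionally also the complementary
#' negative-gate row (1 - p), and a leading all-cells row of ones modelling an
#' unsorted sample.
#'
#' @param intensities numeric matrix, cells x reporters, rows aligned with
#'   the lineage-tree cell order; colnames are reporter names.
#' @param reporters ordered character vector of reporters to use (defaults to
#'   all columns).
#' @param includeNegative also add a negative-gate row per reporter.
#' @param includeAll prepend an all-cells row of ones (default TRUE).
#' @param tree optional [LineageTree-class] used to check alignment and to
#'   name columns.
#' @param intensityParams optional list overriding the mixture parameters
#'   (\code{meanOff}, \code{meanOn}, \code{sd}).
#' @return a [SortMatrix-class].
#' @export
buildSortMatrix <- function(intensities, reporters = colnames(intensities),
                            includeNegative = FALSE, includeAll = TRUE,
                            tree = NULL, intensityParams = list()) {
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities)))
    stop("intensity matrix must have reporter column names")
  missing <- setdiff(reporters, colnames(intensities))
  if (length(missing) > 0L)
    stop("unknown reporter(s): ", paste(missing, collapse = ", "))
  if (!is.null(tree)) {
    if (nrow(intensities) != nCells(tree))
      stop(sprintf("intensity rows (%d) do not match tree cells (%d)",
                   nrow(intensities), nCells(tree)))
    if (!is.null(rownames(intensities)) &&
        !identical(rownames(intensities), cellNames(tree)))
      stop("intensity row names do not match tree cell order")
    cells <- cellNames(tree)
  } else {
    cells <- rownames(intensities)
    if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(intensities)))
  }
  p <- do.call(intensityToOnProbability,
               c(list(intensity = intensities[, reporters, drop = FALSE]),
                 intensityParams))
  p <- matrix(p, nrow = nrow(intensities),
              dimnames = list(cells, reporters))
  rows <- list(); info <- list()
  if (includeAll) {
    rows$all <- rep(1, nrow(p))
    info$all <- data.frame(fraction = "all", reporter = NA_character_,
                           polarity = "all", stringsAsFactors = FALSE)
  }
  for (r in reporters) {
    idp <- paste0(r, "+")
    rows[[idp]] <- p[, r]
    info[[idp]] <- data.frame(fraction = idp, reporter = r,
                              polarity = "positive", stringsAsFactors = FALSE)
    if (includeNegative) {
      idn <- paste0(r, "-")
      rows[[idn]] <- 1 - p[, r]
      info[[idn]] <- data.frame(fraction = idn, reporter = r,
                                polarity = "negative",
                                stringsAsFactors = FALSE)
    }
  }
  A <- do.call(rbind, rows)
  colnames(A) <- cells
  obj <- new("SortMatrix", A = A, fractionInfo = do.call(rbind, info))
  validObject(obj)
  obj
}

#' Simulate fraction measurements b = A x
#'
#' The measured total expression of a gene in a fraction is the linear
#' combination of its expression in the fraction's constituent cells,
#' weighted by the sort-matrix membership probabilities.
#'
#' @param A a [SortMatrix-class] (m fractions x n cells).
#' @param X an [ExpressionMatrix-class] (genes x n cells) or a numeric
#'   matrix/vector.
#' @return a [FractionMeasurements-class] (genes x m fractions).
#' @export
simulateMeasurements <- function(A, X) {
  Amat <- if (is(A, "SortMatrix")) A@A else as.matrix(A)
  Xmat <- if (is(X, "ExpressionMatrix")) X@X else
    if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(Xmat) != ncol(Amat))
    stop(sprintf("expression has %d cells but sort matrix has %d columns",
                 ncol(Xmat), ncol(Amat)))
  b <- Xmat %*% t(Amat)
  colnames(b) <- rownames(Amat)
  new("FractionMeasurements", b = pmax(b, 0))
}

## -- the three experimental-noise perturbations ----------------------------

# draw random (fraction, sublineage) blocks until >= nEntries entries touched
.drawLineageBlocks <- function(A, tree, nEntries, perFraction) {
  masks <- sublineages(tree, minCells = 1L)
  m <- nrow(A)
  picks <- list()
  total <- 0L
  while (total < nEntries) {
    li <- sample.int(length(masks), 1L)
    fr <- if (perFraction) sample.int(m, 1L) else NA_integer_
    k <- sum(masks[[li]])
    picks[[length(picks) + 1L]] <- list(mask = masks[[li]], fraction = fr)
    total <- total + if (perFraction) k else k * m
  }
  picks
}

#' Perturb a sort matrix by flipping lineage blocks
#'
#' Models systematic sort error: cells of a random sublineage end up in the
#' wrong gate of one fraction. Random (fraction, sublineage) blocks are drawn
#' and each entry \eqn{\alpha} in the block is replaced by \eqn{1-\alpha},
#' until at least \code{nEntries} entries have been perturbed.
#'
#' @param A a [SortMatrix-class].
#' @param tree the [LineageTree-class] the columns are indexed by.
#' @param nEntries target number of perturbed entries (>= 0).
#' @param seed integer seed.
#' @return list with \code{A} (the perturbed [SortMatrix-class]) and
#'   \code{nPerturbed} (entries actually flipped, >= \code{nEntries}).
#' @export
perturbFlipLineageEntries <- function(A, tree, nEntries, seed = 1L) {
  stopifnot(is(A, "SortMatrix"), nEntries >= 0)
  if (nEntries == 0) return(list(A = A, nPerturbed = 0L))
  set.seed(seed)
  picks <- .drawLineageBlocks(A@A, tree, nEntries, perFraction = TRUE)
  Anew <- A@A
  total <- 0L
  for (p in picks) {
    Anew[p$fraction, p$mask] <- 1 - Anew[p$fraction, p$mask]
    total <- total + sum(p$mask)
  }
  out <- new("SortMatrix", A = Anew, fractionInfo = A@fractionInfo)
  validObject(out)
  list(A = out, nPerturbed = total)
}

#' Perturb a sort matrix by dropping lineage blocks of cells
#'
#' Models cells lost during dissociation or FACS: random sublineages are
#' drawn and their columns are zeroed across ALL fractions (including the
#' all-cells row), until at least \code{nEntries} entries have been zeroed.
#'
#' @inheritParams perturbFlipLineageEntries
#' @return list with \code{A} and \code{nPerturbed} as in
#'   [perturbFlipLineageEntries()].
#' @export
perturbDropCells <- function(A, tree, nEntries, seed = 1L) {
  stopifnot(is(A, "SortMatrix"), nEntries >= 0)
  if (nEntries == 0) return(list(A = A, nPerturbed = 0L))
  set.seed(seed)
  picks <- .drawLineageBlocks(A@A, tree, nEntries, perFraction = FALSE)
  Anew <- A@A
  total <- 0L
  for (p in picks) {
    Anew[, p$mask] <- 0
    total <- total + sum(p$mask) * nrow(Anew)
  }
  out <- new("SortMatrix", A = Anew, fractionInfo = A@fractionInfo)
  validObject(out)
  list(A = out, nPerturbed = total)
}

#' Perturb measurements with multiplicative noise
#'
#' Each measurement is multiplied by an independent draw from N(1, s^2),
#' modelling biological and technical variability of the fraction totals;
#' negative products are clamped to 0 since totals are physically
#' non-negative.
#'
#' @param b a [FractionMeasurements-class] or numeric matrix.
#' @param s noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return a [FractionMeasurements-class].
#' @export
perturbMeasurementNoise <- function(b, s, seed = 1L) {
  if (s < 0) stop("s must be >= 0")
  bmat <- if (is(b, "FractionMeasurements")) b@b else as.matrix(b)
  if (s == 0) return(new("FractionMeasurements", b = bmat))
  set.seed(seed)
  mult <- matrix(stats::rnorm(length(bmat), mean = 1, sd = s),
                 nrow = nrow(bmat))
  new("FractionMeasurements", b = pmax(bmat * mult, 0))
}

#' Simulate reporter intensities on a lineage
#'
#' Emulates lineage-tracing measurements of fluorescent reporter strains.
#' Real reporters are typically expressed in broad, lineage-structured
#' territories (unions of sublineage blocks covering sizeable portions of
#' the embryo), so by default each simulated reporter is "on" in a union of
#' randomly chosen sublineages grown until a target coverage (drawn
#' uniformly from \code{coverage}) is reached. With \code{coverage = NULL}
#' each reporter is instead on in a single random sublineage. Intensities
#' are drawn from the bimodal two-Gaussian model (off: N(meanOff, sd), on:
#' N(meanOn, sd)) that [intensityToOnProbability()] inverts.
#'
#' @param tree a [LineageTree-class].
#' @param nReporters number of reporter strains to simulate.
#' @param minCells minimum size of each constituent "on" sublineage
#'   (default 2).
#' @param coverage length-2 numeric range of target on-cell coverage
#'   (default c(0.15, 0.5)), or NULL for single-sublineage reporters.
#' @param meanOff,meanOn,sd intensity model parameters (defaults 0, 2000,
#'   1000).
#' @param seed integer seed.
#' @return cells x reporters numeric matrix, rows in tree order; the true
#'   on-masks are stored in \code{attr(, "onMask")} (cells x reporters
#'   logical).
#' @export
simulateReporterIntensities <- function(tree, nReporters, minCells = 2L,
                                        coverage = c(0.15, 0.5),
                                        meanOff = 0, meanOn = 2000,
                                        sd = 1000, seed = 1L) {
  set.seed(seed)
  masks <- sublineages(tree, minCells = minCells)
  # drop the whole-tree mask: an always-on reporter carries no information
  masks <- masks[vapply(masks, function(m) !all(m), logical(1))]
  if (length(masks) == 0L) stop("no usable sublineages for reporters")
  n <- nCells(tree)
  M <- matrix(0, nrow = n, ncol = nReporters,
              dimnames = list(cellNames(tree),
                              paste0("rep", seq_len(nReporters))))
  onMask <- matrix(FALSE, nrow = n, ncol = nReporters,
                   dimnames = dimnames(M))
  for (r in seq_len(nReporters)) {
    if (is.null(coverage)) {
      on <- masks[[sample.int(length(masks), 1L)]]
    } else {
      target <- stats::runif(1, coverage[1L], coverage[2L])
      on <- logical(n)
      while (mean(on) < target)
        on <- on | masks[[sample.int(length(masks), 1L)]]
    }
    M[on, r] <- stats::rnorm(sum(on), meanOn, sd)
    M[!on, r] <- stats::rnorm(sum(!on), meanOff, sd)
    onMask[, r] <- on
  }
  attr(M, "onMask") <- onMask
  M
}

#' Expression patterns matching a set of reporters
#'
#' Builds the synthetic analogue of a "measured expression" benchmark: one
#' on/off gene per reporter, on exactly where the reporter is on, with
#' values drawn from the same normal on/off model as
#' [simulateLineagePatterns()]. Used with the leave-gene-out rule these
#' genes play the role of known reporter patterns that are both ground
#' truth and sort markers.
#'
#' @param intensities output of [simulateReporterIntensities()] (must carry
#'   the \code{onMask} attribute).
#' @param params,seed as in [simulateLineagePatterns()].
#' @return an [ExpressionMatrix-class] with one gene per reporter (same
#'   names), plus attribute-free truth masks.
#' @export
reporterExpressionPatterns <- function(intensities, params = list(),
                                       seed = 1L) {
  onMask <- attr(intensities, "onMask")
  if (is.null(onMask))
    stop("intensities must carry an 'onMask' attribute")
  defaults <- list(onMean = 10, onVar = 11, offMean = 0, offVar = 1)
  p <- utils::modifyList(defaults, params)
  set.seed(seed)
  X <- matrix(0, ncol(onMask), nrow(onMask),
              dimnames = list(colnames(onMask), rownames(onMask)))
  for (g in seq_len(nrow(X))) {
    on <- onMask[, g]
    X[g, on] <- stats::rnorm(sum(on), p$onMean, sqrt(p$onVar))
    X[g, !on] <- stats::rnorm(sum(!on), p$offMean, sqrt(p$offVar))
  }
  new("ExpressionMatrix", X = pmax(X, 0), truthMask = t(onMask))
}
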