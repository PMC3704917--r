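# Shared fixtures: the printed 5x16 example system, small trees, and the
# independent oracles used to pin expected values.

# The worked 5x16 example: an all-cells fraction plus four binary reporters
# that successively bisect 16 cells.
printedSystemRows <- function() {
  rbind(
    all  = rep(1, 16),
    rep1 = as.numeric(strsplit("1111111100000000", "")[[1]]),
    rep2 = as.numeric(strsplit("1111000011110000", "")[[1]]),
    rep3 = as.numeric(strsplit("0011001100110011", "")[[1]]),
    rep4 = as.numeric(strsplit("1000100010001000", "")[[1]]))
}

# saturated intensities (+/- 1e6) reproduce the binary rows exactly through
# the logistic intensity model
printedSystemIntensities <- function() {
  P <- printedSystemRows()[-1, , drop = FALSE]
  t(ifelse(P == 1, 1e6, -1e6))
}

# mirrored tree with 2 * nLeafPairs terminal cells (15 cells for 4 pairs)
mirroredTree <- function(nLeafPairs, seed = 1L, jitter = 0L) {
  generateSyntheticLineage(nLeafPairs, depthJitter = jitter, seed = seed)
}

# minimum-norm solution oracle: direct SVD solve, independent of .pinv
svdMinNormOracle <- function(A, b) {
  sv <- svd(A)
  keep <- sv$d > 1e-12 * max(sv$d)
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep]))
}

# full pseudoinverse matrix by SVD (oracle form of the same computation)
svdMinNormOracle2 <- function(A) {
  sv <- svd(A)
  keep <- sv$d > 1e-12 * max(sv$d)
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# exhaustive active-set oracle for min ||x|| s.t. Ax = b, x >= 0 (n small):
# fix every subset of coordinates at zero, solve the least-norm equality
# problem on the rest, keep the best feasible candidate
activeSetOracle <- function(A, b, tol = 1e-8) {
  n <- ncol(A)
  best <- NULL
  bestNorm <- Inf
  for (code in 0:(2^n - 1)) {
    free <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    if (length(free) > 0) {
      xf <- svdMinNormOracle(A[, free, drop = FALSE], b)
      x[free] <- xf
    }
    if (sqrt(sum((A %*% x - b)^2)) > tol * max(1, sqrt(sum(b^2)))) next
    if (min(x) < -tol) next
    nrm <- sum(x^2)
    if (nrm < bestNorm - 1e-12) { bestNorm <- nrm; best <- x }
  }
  best
}

# random sort-matrix-like instance with n <= 4 and a feasible b
randomSmallInstance <- function(n, m, seed) {
  set.seed(seed)
  A <- matrix(ifelse(runif(m * n) < 0.5, 0, 1), m, n)
  A[1, ] <- 1                               # all-cells row keeps it bounded
  soft <- runif(m * n) < 0.3
  A[soft] <- A[soft] * runif(sum(soft), 0.2, 1)
  x <- ifelse(runif(n) < 0.3, 0, runif(n, 0, 3))
  list(A = A, b = as.numeric(A %*% x), x = x)
}

# shared large-scale study fixture for the reference-scale benchmarks;
# built lazily once per test run and cached
.studyCache <- new.env(parent = emptyenv())

studyFixture <- function() {
  if (!is.null(.studyCache$fx)) return(.studyCache$fx)
  syn <- generateSyntheticLineage(64, depthJitter = 0L, seed = 11)
  tree <- syn$tree
  oneLineage <- simulateLineagePatterns(tree, syn$symmetry, mode = "one",
                                        minCells = 5, seed = 12)
  intensities <- simulateReporterIntensities(tree, 60, minCells = 2,
                                             seed = 13)
  sel <- greedySelect(colnames(intensities), intensities, tree,
                      oneLineage, k = 51, seed = 14)
  .studyCache$fx <- list(tree = tree, symmetry = syn$symmetry,
                         oneLineage = oneLineage,
                         intensities = intensities,
                         order = sel$reporter, objective = sel$objective)
  .studyCache$fx
}

meanAucOverGenes <- function(est, TM) {
  ok <- apply(TM, 1, function(r) any(r) && !all(r))
  mean(vapply(which(ok), function(g) rocAuc(est[g, ], TM[g, ]), numeric(1)))
}
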