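test_that("truncateNegative clamps elementwise at zero", {
  expect_equal(truncateNegative(c(-1, 0, 3.2)), c(0, 0, 3.2))
})

test_that("shrunkenCorrelation blends the sample correlation with identity", {
  X <- matrix(c(1, 2, 3,
                2, 4, 5,
                1, 0, 2,
                5, 3, 8), 4, 3, byrow = TRUE)
  Rhat <- cor(X)
  m <- shrunkenCorrelation(X, lambda = 0.05)
  expect_equal(diag(m@sigma), rep(1, 3), ignore_attr = TRUE)
  off <- row(Rhat) != col(Rhat)
  expect_equal(m@sigma[off], 0.95 * Rhat[off])
  # lambda = 1 gives the identity
  expect_equal(shrunkenCorrelation(X, 1)@sigma, diag(3),
               ignore_attr = TRUE)
  # lambda = 0 with two genes: off-diagonals are +/- 1
  X2 <- matrix(c(1, 2, 3, 6, 5, 4), 2, 3, byrow = TRUE)
  m0 <- shrunkenCorrelation(X2, 0)
  expect_true(all(abs(abs(m0@sigma[row(m0@sigma) != col(m0@sigma)]) - 1) <
                    1e-12))
  # zero-variance cell: warning, correlations zeroed
  X3 <- cbind(X, 0)
  expect_warning(m3 <- shrunkenCorrelation(X3, 0.05), "zero-variance")
  expect_equal(m3@sigma[4, 1:3], rep(0, 3), ignore_attr = TRUE)
  expect_equal(m3@sigma[4, 4], 1)
  expect_error(shrunkenCorrelation(X[1, , drop = FALSE]), ">= 2 genes")
})

test_that("correlated patterns are truncated MVN draws with gene count", {
  m <- new("CorrelationModel", sigma = diag(4), lambda = 1)
  X <- simulateCorrelatedPatterns(m, nGenes = 4000, seed = 3)
  expect_equal(nrow(exprValues(X)), 4000L)
  expect_null(truthMask(X))
  # with Sigma = I about half of all entries are truncated zeros
  expect_equal(mean(exprValues(X) == 0), 0.5, tolerance = 0.02)
  # default gene count is 200
  expect_equal(nrow(exprValues(simulateCorrelatedPatterns(m, seed = 1))),
               200L)
  # perfectly correlated cells get equal values where positive
  S <- matrix(c(1, 1, 1, 1), 2, 2)
  Xp <- exprValues(simulateCorrelatedPatterns(S, nGenes = 50, seed = 4))
  pos <- Xp[, 1] > 0 & Xp[, 2] > 0
  expect_true(any(pos))
  expect_equal(Xp[pos, 1], Xp[pos, 2], tolerance = 1e-4)
  # non-PSD covariance is rejected with an eigenvalue report
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulateCorrelatedPatterns(bad, 10), "eigenvalue")
})

test_that("lineage patterns emit one gene per qualifying mask with truth", {
  syn <- mirroredTree(4)          # 15 cells
  X <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                               minCells = 5, seed = 1)
  expect_equal(nrow(exprValues(X)), 3L)
  expect_setequal(rowSums(truthMask(X)), c(15L, 7L, 7L))
  Xp <- simulateLineagePatterns(syn$tree, syn$symmetry,
                                mode = "two_symmetric", minCells = 5,
                                seed = 1)
  expect_equal(nrow(exprValues(Xp)), 1L)    # only the (L, R) pair
  expect_equal(sum(truthMask(Xp)), 14L)
  expect_warning(
    empty <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                                     minCells = 100, seed = 1),
    "no qualifying")
  expect_equal(nrow(exprValues(empty)), 0L)
})

test_that("on cells are brighter than off cells under default parameters", {
  syn <- mirroredTree(32, seed = 2)
  X <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                               minCells = 5, seed = 5)
  V <- exprValues(X); TM <- truthMask(X)
  sep <- vapply(seq_len(nrow(V)), function(g) {
    if (all(TM[g, ])) return(TRUE)
    mean(V[g, TM[g, ]]) > mean(V[g, !TM[g, ]])
  }, logical(1))
  expect_gte(mean(sep), 0.99)
  expect_true(all(V >= 0))
  # the transposed parameterization swaps on and off
  Xl <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                                minCells = 5, seed = 5,
                                literalParameterization = TRUE)
  Vl <- exprValues(Xl)
  g <- which(!apply(TM, 1, all))[1]
  expect_gt(mean(Vl[g, !TM[g, ]]), mean(Vl[g, TM[g, ]]))
})

test_that("gamma noise uses Gamma(1,1) off cells", {
  syn <- mirroredTree(64, seed = 2)
  X <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                               minCells = 5, noise = "gamma",
                               params = list(onShape = 10, onScale = 1),
                               seed = 6)
  V <- exprValues(X); TM <- truthMask(X)
  offs <- V[!TM]
  expect_gt(length(offs), 1e4)
  expect_equal(mean(offs), 1, tolerance = 3 / sqrt(length(offs)) + 0.01)
  expect_true(all(V >= 0))
})

test_that("reporter-derived patterns mirror the reporter on-masks", {
  syn <- mirroredTree(16)
  ints <- simulateReporterIntensities(syn$tree, 8, seed = 3)
  X <- reporterExpressionPatterns(ints, seed = 4)
  expect_equal(dim(exprValues(X)), c(8L, nCells(syn$tree)))
  expect_equal(unname(truthMask(X)), unname(t(attr(ints, "onMask"))))
  expect_true(all(exprValues(X) >= 0))
})

test_that("expression TSVs round-trip with truth masks", {
  syn <- mirroredTree(4)
  X <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                               minCells = 5, seed = 1)
  path <- tempfile(fileext = ".tsv")
  writeExpressionTSV(X, path)
  X2 <- readExpressionTSV(path)
  expect_equal(exprValues(X2), exprValues(X), tolerance = 1e-9)
  expect_equal(truthMask(X2), truthMask(X))
})
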