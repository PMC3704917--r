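test_that("rocAuc implements the midrank Mann-Whitney statistic", {
  expect_equal(rocAuc(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(c(2, 3, 4, 5), c(1, 1, 0, 0)), 0)
  expect_equal(rocAuc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  # ties handled by midranks
  expect_equal(rocAuc(c(1, 1, 0), c(1, 0, 0)), 0.75)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "undefined")
  # invariance under strictly monotone transforms
  set.seed(1)
  p <- runif(50); t <- rbinom(50, 1, 0.4)
  expect_equal(rocAuc(p, t), rocAuc(exp(3 * p) - 1, t))
  expect_equal(rocAuc(p, t), rocAuc(rank(p), t))
})

test_that("rocAuc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:5) {
    p <- runif(60); t <- rbinom(60, 1, 0.5)
    if (length(unique(t)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(t, p,
                                                 direction = "<")))
    expect_equal(rocAuc(p, t), ref, tolerance = 1e-10)
  }
})

test_that("pearsonAccuracy matches closed-form small cases", {
  expect_equal(pearsonAccuracy(1:5, 1:5), 1)
  expect_equal(pearsonAccuracy(1:5, 5:1), -1)
  expect_equal(pearsonAccuracy(c(1, 2, 3), c(1, 2, 4)), 0.9820,
               tolerance = 1e-4)
  expect_error(pearsonAccuracy(rep(1, 3), 1:3), "constant")
})

test_that("calibrationZ scales truth by prediction moments with clipping", {
  z <- calibrationZ(truth = c(1, 3, 1, 9), mean = c(1, 1, 1, 1),
                    sd = c(1, 1, 0, 0))
  expect_equal(z$z[1], 0)
  expect_equal(z$z[2], 2)
  expect_equal(z$z[3], 0)          # sd = 0 but truth equals mean
  expect_equal(z$z[4], Inf)        # raw value retained
  expect_equal(z$zClipped[4], 5)   # reported at the clip
  expect_equal(calibrationZ(0, 10, 1)$zClipped, -5)
  expect_error(calibrationZ(1, 1, -1), "non-negative")
})

test_that("resolution matrix is the projector onto the row space", {
  # square full rank: identity
  set.seed(3)
  A <- matrix(runif(16), 4, 4) + diag(4)
  expect_equal(resolutionMatrix(A), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the single-fraction case
  expect_equal(resolutionMatrix(matrix(c(1, 1), 1)),
               matrix(0.5, 2, 2), tolerance = 1e-12, ignore_attr = TRUE)
  # projector algebra on random rectangular instances
  for (seed in 4:8) {
    set.seed(seed)
    m <- sample(2:6, 1); n <- sample(m:10, 1)
    A <- matrix(rbinom(m * n, 1, 0.5), m, n)
    R <- resolutionMatrix(A)
    expect_equal(R %*% R, R, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(R, t(R), tolerance = 1e-8, ignore_attr = TRUE)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(abs(ev) < 1e-8 | abs(ev - 1) < 1e-8))
    expect_equal(sum(diag(R)), qr(A)$rank, tolerance = 1e-8)
  }
})

test_that("expression weighting scales resolution columns", {
  R <- resolutionMatrix(matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(expressionWeightedResolution(R, rep(1, 3)), R)
  w <- expressionWeightedResolution(R, c(0, 1, 0))
  expect_equal(w[, c(1, 3)], matrix(0, 3, 2), ignore_attr = TRUE)
  expect_equal(w[, 2], R[, 2])
  x <- c(2, 5, 1)
  expect_equal(rowSums(expressionWeightedResolution(R, x)),
               as.numeric(R %*% x))
  expect_error(expressionWeightedResolution(R, 1:4), "length")
})

test_that("a full-rank noise-free benchmark recovers every gene perfectly", {
  syn <- mirroredTree(8)                 # 31 cells
  tree <- syn$tree
  # one binary reporter per cell, on exactly on its subtree: the 31 subtree
  # indicators are linearly independent, so the system is fully determined
  ints <- do.call(cbind, lapply(cellNames(tree), function(cn)
    ifelse(lineageMask(tree, cn), 1e6, -1e6)))
  colnames(ints) <- paste0("sub_", cellNames(tree))
  onM <- sapply(cellNames(tree), function(cn) lineageMask(tree, cn))
  attr(ints, "onMask") <- onM
  X <- simulateLineagePatterns(tree, syn$symmetry, mode = "one",
                               minCells = 5, seed = 2)
  res <- runBenchmark(tree, X, ints, colnames(ints),
                      counts = ncol(ints), methods = "naive", seed = 3)
  aucs <- res$perGene$auc
  expect_true(all(is.na(aucs) | aucs == 1))
  expect_true(any(aucs == 1, na.rm = TRUE))
  expect_true(all(res$summary$n_failed == 0))
})

test_that("benchmark scores degrade with sort-flip perturbations", {
  syn <- mirroredTree(16, seed = 21)     # 63 cells, fast
  X <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                               minCells = 5, seed = 22)
  ints <- simulateReporterIntensities(syn$tree, 20, seed = 23)
  fo <- colnames(ints)
  clean <- runBenchmark(syn$tree, X, ints, fo, counts = 15L,
                        methods = "naive", seed = 24)
  noisy <- runBenchmark(syn$tree, X, ints, fo, counts = 15L,
                        methods = "naive",
                        noise = list(type = "flip", nEntries = 150),
                        seed = 24)
  expect_gt(clean$summary$mean_auc, noisy$summary$mean_auc)
  expect_gt(clean$summary$mean_pearson, noisy$summary$mean_pearson)
})

test_that("the leave-gene-out rule swaps the gene's own reporter", {
  syn <- mirroredTree(8, seed = 31)
  ints <- simulateReporterIntensities(syn$tree, 6, seed = 32)
  X <- reporterExpressionPatterns(ints, seed = 33)
  grm <- setNames(colnames(ints), colnames(ints))
  # without the rule the gene's own marker makes it trivially easy; the
  # rule must still produce a full result table using the spare reporter
  res <- runBenchmark(syn$tree, X, ints, colnames(ints), counts = 5L,
                      methods = "naive", geneReporterMap = grm, seed = 34)
  expect_equal(nrow(res$perGene), 6L)
  expect_true(all(is.finite(res$perGene$pearson)))
  # demanding more fractions than the order can supply (with the spare
  # reserved) is rejected
  expect_error(runBenchmark(syn$tree, X, ints, colnames(ints),
                            counts = 6L, methods = "naive",
                            geneReporterMap = grm, seed = 34),
               "spare|cover")
})

test_that("paired method comparison applies Bonferroni correction", {
  set.seed(41)
  genes <- paste0("g", 1:30)
  better <- data.frame(dataset = "d", method = "A", n_fractions = 10,
                       gene = genes, auc = runif(30, 0.8, 1),
                       pearson = 0.9, failed = FALSE)
  worse <- better
  worse$method <- "B"
  worse$auc <- better$auc - runif(30, 0.05, 0.15)
  cmp <- pairedMethodComparison(rbind(better, worse), metric = "auc")
  expect_equal(nrow(cmp), 1L)
  expect_gt(cmp$mean_diff, 0)
  expect_true(cmp$significant)
  # a fixed Bonferroni denominator scales the corrected p-value
  cmp24 <- pairedMethodComparison(rbind(better, worse), metric = "auc",
                                  nTests = 24)
  expect_equal(cmp24$p_bonferroni, pmin(cmp$p * 24, 1))
})
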