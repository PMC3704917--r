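test_that("intensity-to-probability follows the two-Gaussian logistic", {
  expect_equal(intensityToOnProbability(1000), 0.5)
  expect_equal(intensityToOnProbability(2000), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(intensityToOnProbability(0), 1 / (1 + exp(2)),
               tolerance = 1e-12)
  xs <- seq(-5000, 8000, by = 250)
  ps <- intensityToOnProbability(xs)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
  expect_error(intensityToOnProbability(NaN), "finite")
})

test_that("buildSortMatrix reproduces the printed 5x16 example system", {
  A <- buildSortMatrix(printedSystemIntensities())
  expect_equal(unname(sortValues(A)), unname(printedSystemRows()))
  expect_equal(fractionInfo(A)$polarity,
               c("all", rep("positive", 4)))
})

test_that("buildSortMatrix handles probabilistic rows and negative gates", {
  ints <- matrix(1000, nrow = 16, ncol = 1,
                 dimnames = list(NULL, "repA"))
  A <- buildSortMatrix(ints)
  expect_equal(unname(sortValues(A)["repA+", ]), rep(0.5, 16))
  set.seed(5)
  ints2 <- matrix(rnorm(32, 1000, 800), 16, 2,
                  dimnames = list(NULL, c("r1", "r2")))
  An <- buildSortMatrix(ints2, includeNegative = TRUE)
  expect_equal(sortValues(An)["r1-", ], 1 - sortValues(An)["r1+", ])
  expect_error(buildSortMatrix(ints2, reporters = "r3"), "unknown reporter")
})

test_that("simulateMeasurements computes b = Ax and is linear", {
  A <- buildSortMatrix(printedSystemIntensities())
  e1 <- c(1, rep(0, 15))
  b <- measurementValues(simulateMeasurements(A, e1))
  expect_equal(unname(b[1, ]), c(1, 1, 1, 0, 1))
  expect_equal(unname(measurementValues(
    simulateMeasurements(A, rep(0, 16)))[1, ]), rep(0, 5))
  # identity sort matrix returns x itself
  I16 <- new("SortMatrix", A = diag(16),
             fractionInfo = data.frame(fraction = paste0("f", 1:16),
                                       reporter = NA, polarity = "positive"))
  set.seed(1); x <- runif(16)
  expect_equal(unname(measurementValues(simulateMeasurements(I16, x))[1, ]),
               x)
  # linearity
  set.seed(2); y <- runif(16)
  bx <- measurementValues(simulateMeasurements(A, x))
  by <- measurementValues(simulateMeasurements(A, y))
  bxy <- measurementValues(simulateMeasurements(A, x + y))
  expect_equal(bxy, bx + by, tolerance = 1e-12)
  b3 <- measurementValues(simulateMeasurements(A, 3 * x))
  expect_equal(b3, 3 * bx, tolerance = 1e-12)
  expect_error(simulateMeasurements(A, runif(10)), "cells")
})

test_that("the printed system distinguishes single-cell patterns by signature", {
  A <- printedSystemRows()
  sig <- apply(A, 2, paste, collapse = ",")
  for (j in 1:16) for (k in 1:16) {
    if (j == k) next
    if (sig[j] != sig[k]) {
      bj <- A %*% replace(rep(0, 16), j, 1)
      bk <- A %*% replace(rep(0, 16), k, 1)
      expect_false(isTRUE(all.equal(bj, bk)))
    }
  }
})

test_that("flip perturbation is a seeded involution within [0,1]", {
  syn <- mirroredTree(8)
  ints <- simulateReporterIntensities(syn$tree, 6, seed = 4)
  A <- buildSortMatrix(ints, tree = syn$tree)
  expect_identical(perturbFlipLineageEntries(A, syn$tree, 0)$A, A)
  pf <- perturbFlipLineageEntries(A, syn$tree, 10, seed = 9)
  expect_gte(pf$nPerturbed, 10)
  expect_true(any(sortValues(pf$A) != sortValues(A)))
  expect_true(all(sortValues(pf$A) >= 0 & sortValues(pf$A) <= 1))
  # same seed picks the same blocks: applying twice restores the original
  pf2 <- perturbFlipLineageEntries(pf$A, syn$tree, 10, seed = 9)
  expect_equal(sortValues(pf2$A), sortValues(A), tolerance = 1e-12)
})

test_that("drop perturbation zeroes whole columns across all fractions", {
  syn <- mirroredTree(8)
  ints <- simulateReporterIntensities(syn$tree, 6, seed = 4)
  A <- buildSortMatrix(ints, tree = syn$tree)
  expect_identical(perturbDropCells(A, syn$tree, 0)$A, A)
  pd <- perturbDropCells(A, syn$tree, 20, seed = 2)
  Ad <- sortValues(pd$A)
  zeroed <- which(colSums(Ad) == 0)
  expect_gte(length(zeroed), 1L)
  # bookkeeping counts cells x fractions for the chosen lineages
  expect_equal(pd$nPerturbed %% nrow(Ad), 0)
  expect_gte(pd$nPerturbed, 20)
  # untouched columns are unchanged (chosen masks are whole sublineages)
  touched <- colSums(Ad != sortValues(A)) > 0
  expect_true(all(Ad[, touched] == 0))
  expect_equal(Ad[, !touched], sortValues(A)[, !touched])
})

test_that("measurement noise is multiplicative N(1, s^2) clamped at zero", {
  b <- matrix(runif(40, 1, 10), 4, 10)
  expect_equal(measurementValues(perturbMeasurementNoise(b, 0)), b)
  n1 <- measurementValues(perturbMeasurementNoise(b, 0.3, seed = 5))
  n2 <- measurementValues(perturbMeasurementNoise(b, 0.3, seed = 5))
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))
  # empirical multiplier mean over 1e5 draws is 1 within 3 standard errors
  big <- matrix(1, 1, 1e5)
  mult <- measurementValues(perturbMeasurementNoise(big, 0.5, seed = 6))
  # clamping truncates the lower tail: compare against the clamped mean
  clampedMean <- mean(pmax(rnorm(2e5, 1, 0.5), 0))
  expect_lt(abs(mean(mult) - clampedMean), 3 * 0.5 / sqrt(1e5) + 0.002)
  expect_error(perturbMeasurementNoise(b, -1), ">= 0")
})

test_that("simulated reporters are broad lineage-structured territories", {
  syn <- mirroredTree(32)
  ints <- simulateReporterIntensities(syn$tree, 20, seed = 8)
  onM <- attr(ints, "onMask")
  cov <- colMeans(onM)
  expect_true(all(cov > 0.05 & cov < 0.9))
  # single-sublineage mode: each on-set is exactly one rooted subtree
  ints1 <- simulateReporterIntensities(syn$tree, 10, coverage = NULL,
                                       seed = 8)
  on1 <- attr(ints1, "onMask")
  subtreeSets <- sublineages(syn$tree, 1)
  for (r in seq_len(ncol(on1))) {
    match <- any(vapply(subtreeSets, function(m) identical(unname(m),
                                                           unname(on1[, r])),
                        logical(1)))
    expect_true(match)
  }
})
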