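test_that("EP recovers point-constrained and segment polytopes", {
  # single cell pinned by the measurement
  r1 <- epDeconvolve(matrix(1, 1, 1), 5)
  expect_equal(unname(posteriorMean(r1)), 5, tolerance = 0.01)
  expect_lt(posteriorSd(r1), 0.01)
  expect_true(r1@converged)
  # segment x1 + x2 = 1: coordinates ~ U(0,1), mean 0.5, sd 1/sqrt(12)
  r2 <- epDeconvolve(matrix(c(1, 1), 1), 1)
  expect_equal(unname(posteriorMean(r2)), c(0.5, 0.5), tolerance = 0.02)
  sds <- posteriorSd(r2)
  expect_equal(sds[1], sds[2], tolerance = 1e-6)
  # EP moderately overestimates the marginal spread (cf. the factor ~2
  # against sampling); the scale is right
  expect_lt(abs(sds[1] - 1 / sqrt(12)), 0.1)
  expect_error(epDeconvolve(matrix(1, 1, 1), c(1, 2)), "rows")
  expect_error(epDeconvolve(matrix(1, 1, 1), -1), "non-negative")
})

test_that("EP collapses to the unique feasible point of the printed system", {
  A <- buildSortMatrix(printedSystemIntensities())
  b <- measurementValues(simulateMeasurements(A, c(1, rep(0, 15))))[1, ]
  r <- epDeconvolve(A, b)
  expect_equal(unname(posteriorMean(r)), c(1, rep(0, 15)),
               tolerance = 0.02)
  expect_lt(max(posteriorSd(r)), 0.02)
})

test_that("EP means match hit-and-run means on small bounded polytopes", {
  for (seed in c(3, 4, 7, 8, 11)) {
    set.seed(seed)
    n <- sample(3:6, 1); m <- sample(2:3, 1)
    A <- rbind(rep(1, n),
               matrix(ifelse(runif((m - 1) * n) < 0.5, 0, 1), m - 1, n))
    b <- as.numeric(A %*% runif(n, 0, 2))
    ep <- epDeconvolve(A, b)
    ss <- sampleFeasible(A, b, nBurn = 5e3, nIter = 5e4, thin = 5,
                         nChains = 2, seed = seed)
    diam <- 2 * b[1]     # coordinates are bounded by the all-cells total
    expect_lt(max(abs(posteriorMean(ep) - posteriorMean(ss))),
              0.05 * diam)
    keep <- !ss@omitted & posteriorSd(ss) > 0
    if (any(keep))
      expect_gte(mean(posteriorSd(ep)[keep] >= posteriorSd(ss)[keep]), 0.8)
  }
})

test_that("EP is approximately calibrated on the one-lineage benchmark", {
  syn <- mirroredTree(32, seed = 11)
  X <- simulateLineagePatterns(syn$tree, syn$symmetry, mode = "one",
                               minCells = 5, seed = 12)
  ints <- simulateReporterIntensities(syn$tree, 40, seed = 13)
  A <- buildSortMatrix(ints, reporters = colnames(ints)[1:30],
                       tree = syn$tree)
  b <- measurementValues(simulateMeasurements(A, X))
  zs <- c()
  for (g in seq_len(nrow(b))) {
    ep <- epDeconvolve(A, b[g, ], damped = TRUE)
    sd <- posteriorSd(ep)
    k <- sd > 1e-6
    zs <- c(zs, (exprValues(X)[g, k] - posteriorMean(ep)[k]) / sd[k])
  }
  expect_lt(abs(mean(zs)), 0.2)
  expect_lt(sd(zs), 1.5)
})

test_that("damped EP equals undamped EP when the undamped run converges", {
  A <- buildSortMatrix(printedSystemIntensities())
  set.seed(20)
  x <- runif(16, 0, 3)
  b <- measurementValues(simulateMeasurements(A, x))[1, ]
  d <- epDeconvolve(A, b, damped = TRUE)
  u <- epDeconvolve(A, b, damped = FALSE)
  expect_true(u@converged)
  expect_equal(d@finalStep, 1)    # no halving was needed
  expect_equal(posteriorMean(d), posteriorMean(u), tolerance = 1e-8)
  expect_equal(posteriorSd(d), posteriorSd(u), tolerance = 1e-8)
})

test_that("damped EP always returns a result on stress problems", {
  # inconsistent, rank-deficient systems with many boundary cells
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    A <- rbind(rep(1, n), matrix(rbinom(3 * n, 1, 0.5), 3, n))
    A <- rbind(A, A[2, ])                      # duplicated constraint
    b <- c(1, runif(3, 0, 2), runif(1, 0, 2))  # inconsistent duplicate
    r <- epDeconvolve(A, b, damped = TRUE, maxIter = 60)
    expect_s4_class(r, "EPResult")
    expect_true(all(is.finite(posteriorMean(r))))
    expect_true(all(is.finite(posteriorSd(r))))
  }
})

test_that("group summaries aggregate means and covariances correctly", {
  Sig <- matrix(c(1, -0.3, 0, -0.3, 2, 0, 0, 0, 4), 3, 3)
  r <- new("EPResult", mean = c(1, 2, 3), covariance = Sig,
           converged = TRUE, iterations = 1L, finalStep = 1,
           offsetRemoved = TRUE)
  # singleton mask returns the marginal
  s1 <- epGroupSummary(r, c(TRUE, FALSE, FALSE))
  expect_equal(unname(s1), c(1, 1))
  # independent cells: variances add
  s2 <- epGroupSummary(r, c(TRUE, FALSE, TRUE))
  expect_equal(unname(s2), c(4, sqrt(5)))
  # negative covariance narrows the group interval
  s3 <- epGroupSummary(r, c(TRUE, TRUE, FALSE))
  expect_equal(unname(s3), c(3, sqrt(1 + 2 - 2 * 0.3)))
  # average divides mean by k and variance by k^2
  s4 <- epGroupSummary(r, c(TRUE, TRUE, FALSE), statistic = "average")
  expect_equal(unname(s4), c(1.5, sqrt(2.4) / 2))
  expect_error(epGroupSummary(r, c(FALSE, FALSE, FALSE)), "at least one")
})

test_that("EP posteriors serialize to TSV", {
  r <- epDeconvolve(buildSortMatrix(printedSystemIntensities()),
                    c(4, 2, 2, 2, 1))
  path <- tempfile(fileext = ".tsv")
  writePosteriorTSV(r, path, covPath = paste0(path, ".cov"))
  df <- read.delim(path)
  expect_equal(nrow(df), 16L)
  expect_equal(df$mean, unname(posteriorMean(r)), tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".cov")))
})
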