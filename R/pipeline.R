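## End-to-end experiment orchestration: a validated configuration drives
## lineage construction, expression simulation, sort-matrix assembly,
## measurement simulation, deconvolution and artifact output, with a
## manifest capturing everything needed to reproduce the run.

.validationError <- function(msg) {
  stop(structure(class = c("lindeconv_validation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate an experiment configuration
#'
#' A configuration is a named list (or YAML file) with components:
#' \describe{
#'   \item{output_dir}{directory for artifacts (created if missing).}
#'   \item{seed}{base integer seed; every stochastic stage derives from it.}
#'   \item{lineage}{either \code{list(source = "synthetic", n_leaf_pairs =,
#'     depth_jitter =)} or \code{list(source = "file", path =, symmetry_path
#'     =)}.}
#'   \item{expression}{\code{list(design = "one"|"two_symmetric"|
#'     "correlated", min_cells =, noise =, params =, n_genes =)}.}
#'   \item{reporters}{\code{list(n_candidates =)} for simulated reporter
#'     strains, or \code{list(intensities_path =)}.}
#'   \item{fractions}{\code{list(count =, order = NULL|"greedy"|character
#'     vector, include_negative =)}.}
#'   \item{method}{\code{list(name = "naive"|"constrained"|"correlated"|
#'     "ep"|"ep_damped"|"sample", ...hyperparameters)}.}
#'   \item{noise}{optional, as in [runBenchmark()].}
#' }
#'
#' @param config named list or YAML path.
#' @return the normalized config list (invisibly usable by
#'   [runExperiment()]).
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      .validationError(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .validationError("config must be a list")
  for (field in c("output_dir", "lineage", "expression", "reporters",
                  "fractions", "method"))
    if (is.null(config[[field]]))
      .validationError(paste("config is missing field:", field))
  config$seed <- as.integer(config$seed %||% 1L)
  lin <- config$lineage
  if (identical(lin$source, "file")) {
    if (is.null(lin$path) || !file.exists(lin$path))
      .validationError(paste("lineage file not found:",
                             lin$path %||% "<missing>"))
    if (!is.null(lin$symmetry_path) && !file.exists(lin$symmetry_path))
      .validationError(paste("symmetry file not found:", lin$symmetry_path))
  } else if (!identical(lin$source, "synthetic")) {
    .validationError("lineage$source must be 'synthetic' or 'file'")
  }
  rcfg <- config$reporters
  if (!is.null(rcfg$intensities_path) && !file.exists(rcfg$intensities_path))
    .validationError(paste("intensity file not found:",
                           rcfg$intensities_path))
  ok <- c("naive", "constrained", "correlated", "ep", "ep_damped", "sample")
  if (!(config$method$name %in% ok))
    .validationError(paste("unknown method:", config$method$name))
  if (!(config$expression$design %||% "one") %in%
      c("one", "two_symmetric", "correlated"))
    .validationError("expression$design must be one, two_symmetric or correlated")
  config
}

#' Run a configured deconvolution experiment
#'
#' Executes the full pipeline described by the configuration (see
#' [validateConfig()]): build or load the lineage, simulate or load
#' reporter intensities, assemble the sort matrix, generate ground-truth
#' expression, simulate (optionally noisy) fraction measurements,
#' deconvolve every gene with the configured engine, and write all
#' artifacts (TSV tables plus a YAML manifest with package version, config
#' and per-stage timings) under \code{output_dir}. Deterministic given the
#' seeds recorded in the manifest.
#'
#' @param config named list or YAML path, validated by [validateConfig()].
#' @return (invisibly) a list with the in-memory objects: \code{tree},
#'   \code{symmetry}, \code{sortMatrix}, \code{truth}, \code{measurements},
#'   \code{estimates}, \code{posteriors}, \code{manifest}.
#' @export
runExperiment <- function(config) {
  config <- validateConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## lineage
  lin <- config$lineage
  if (identical(lin$source, "synthetic")) {
    syn <- generateSyntheticLineage(lin$n_leaf_pairs %||% 64L,
                                    lin$depth_jitter %||% 0L,
                                    seed = seed)
    tree <- syn$tree; sym <- syn$symmetry
  } else {
    tree <- loadLineage(lin$path)
    sym <- if (!is.null(lin$symmetry_path))
      loadSymmetryMap(lin$symmetry_path, tree) else NULL
  }
  writeLineageTSV(tree, file.path(config$output_dir, "lineage.tsv"),
                  sym = sym,
                  symPath = file.path(config$output_dir, "symmetry.tsv"))
  timings$lineage <- tic() - t0; t0 <- tic()

  ## reporter intensities
  rcfg <- config$reporters
  intensities <- if (!is.null(rcfg$intensities_path)) {
    .readTSVMatrix(rcfg$intensities_path)
  } else {
    simulateReporterIntensities(tree, rcfg$n_candidates %||% 40L,
                                minCells = rcfg$min_cells %||% 2L,
                                seed = seed + 1L)
  }
  timings$reporters <- tic() - t0; t0 <- tic()

  ## ground-truth expression
  ex <- config$expression
  design <- ex$design %||% "one"
  truth <- if (design == "correlated") {
    base <- simulateLineagePatterns(tree, sym, mode = "one",
                                    minCells = ex$min_cells %||% 5L,
                                    seed = seed + 2L)
    model <- shrunkenCorrelation(base, lambda = ex$lambda %||% 0.05)
    simulateCorrelatedPatterns(model, nGenes = ex$n_genes %||% 200L,
                               seed = seed + 3L)
  } else {
    simulateLineagePatterns(tree, sym, mode = design,
                            minCells = ex$min_cells %||% 5L,
                            noise = ex$noise %||% "normal",
                            params = ex$params %||% list(),
                            seed = seed + 2L)
  }
  writeExpressionTSV(truth, file.path(config$output_dir, "truth.tsv"))
  timings$expression <- tic() - t0; t0 <- tic()

  ## sort matrix
  fr <- config$fractions
  order <- fr$order
  if (identical(order, "greedy")) {
    sel <- greedySelect(colnames(intensities), intensities, tree,
                        truth, k = min(fr$count %||% 30L,
                                       ncol(intensities)),
                        includeNegative = isTRUE(fr$include_negative),
                        seed = seed + 4L)
    order <- sel$reporter
  } else if (is.null(order)) {
    order <- colnames(intensities)
  }
  count <- min(fr$count %||% 30L, length(order))
  A <- buildSortMatrix(intensities, reporters = order[seq_len(count)],
                       includeNegative = isTRUE(fr$include_negative),
                       includeAll = TRUE, tree = tree)
  writeSortMatrixTSV(A, file.path(config$output_dir, "sort_matrix.tsv"))
  timings$sort_matrix <- tic() - t0; t0 <- tic()

  ## measurements (with optional perturbations)
  Asim <- A
  if (!is.null(config$noise) && config$noise$type %in% c("flip", "drop")) {
    pfun <- if (config$noise$type == "flip") perturbFlipLineageEntries else
      perturbDropCells
    Asim <- pfun(A, tree, config$noise$nEntries,
                 seed = seed + 5L)$A
  }
  b <- simulateMeasurements(Asim, truth)
  if (!is.null(config$noise) && config$noise$type == "measurement")
    b <- perturbMeasurementNoise(b, config$noise$s, seed = seed + 5L)
  writeMeasurementsTSV(b, file.path(config$output_dir, "measurements.tsv"))
  timings$measurements <- tic() - t0; t0 <- tic()

  ## deconvolution
  method <- config$method$name
  posteriors <- NULL
  nFailed <- 0L
  if (method == "sample") {
    bm <- measurementValues(b)
    posteriors <- lapply(seq_len(nrow(bm)), function(g)
      sampleFeasible(A, bm[g, ],
                     nBurn = config$method$n_burn %||% 1e4,
                     nIter = config$method$n_iter %||% 1e4,
                     thin = config$method$thin %||% 10L,
                     nChains = config$method$n_chains %||% 2L,
                     seed = seed + 6L + g, keepChains = FALSE))
    est <- do.call(rbind, lapply(posteriors, posteriorMean))
    dimnames(est) <- list(rownames(bm), cellNames(tree))
    estimates <- new("ExpressionMatrix", X = pmax(est, 0),
                     truthMask = NULL)
  } else if (method %in% c("ep", "ep_damped")) {
    bm <- measurementValues(b)
    epc <- config$method[setdiff(names(config$method), "name")]
    posteriors <- vector("list", nrow(bm))
    est <- matrix(0, nrow(bm), nCells(tree),
                  dimnames = list(rownames(bm), cellNames(tree)))
    for (g in seq_len(nrow(bm))) {
      fit <- tryCatch(do.call(epDeconvolve,
               c(list(A = A, b = bm[g, ],
                      damped = (method == "ep_damped")), epc)),
               error = function(e) NULL)
      if (is.null(fit)) { nFailed <- nFailed + 1L; next }
      posteriors[[g]] <- fit
      est[g, ] <- pmax(fit@mean, 0)
    }
    estimates <- new("ExpressionMatrix", X = est, truthMask = NULL)
  } else {
    model <- if (method == "correlated")
      shrunkenCorrelation(truth, lambda = config$method$lambda %||% 0.05)
    else NULL
    estimates <- deconvolveMatrix(A, b, method = method, model = model)
  }
  writeExpressionTSV(estimates,
                     file.path(config$output_dir, "estimates.tsv"))
  if (!is.null(posteriors)) {
    ok <- which(!vapply(posteriors, is.null, logical(1)))
    if (length(ok) > 0L)
      writePosteriorTSV(posteriors[[ok[1L]]],
                        file.path(config$output_dir,
                                  "posterior_gene1.tsv"))
  }
  timings$deconvolution <- tic() - t0

  manifest <- list(
    package = "lindeconv",
    version = as.character(utils::packageVersion("lindeconv")),
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    n_cells = nCells(tree), n_genes = nrow(exprValues(truth)),
    n_fractions = nrow(sortValues(A)), n_failed = nFailed,
    timings = timings)
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(list(tree = tree, symmetry = sym, sortMatrix = A,
                 truth = truth, measurements = b, estimates = estimates,
                 posteriors = posteriors, manifest = manifest))
}
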