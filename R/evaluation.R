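## Accuracy metrics, uncertainty calibration, resolution matrices and the
## fraction-count / noise benchmark harness.

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with midrank tie handling: the probability
#' that a randomly chosen expressing ("on") cell receives a higher
#' prediction than a randomly chosen non-expressing cell.
#'
#' @param pred numeric prediction vector.
#' @param truth logical (or 0/1) truth labels; must contain at least one
#'   positive and one negative.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))  # 0.5
#' @export
rocAuc <- function(pred, truth) {
  truth <- as.logical(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: truth must contain both positives and negatives")
  r <- rank(pred)
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Pearson accuracy of a deconvolved pattern
#'
#' @param pred,truth numeric vectors; both must be non-constant.
#' @return Pearson correlation in [-1, 1].
#' @export
pearsonAccuracy <- function(pred, truth) {
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    stop("Pearson accuracy undefined for constant vectors")
  stats::cor(pred, truth)
}

#' Calibration z-scores of predictions
#'
#' Scales the true expression to the mean and standard deviation of the
#' prediction: \eqn{z = (truth - mean)/sd}. Where sd = 0 the z-score is 0
#' when the truth equals the mean and \eqn{\pm}\code{clip} otherwise. Raw
#' values are retained; \code{zClipped} truncates at \eqn{\pm}\code{clip}
#' for reporting.
#'
#' @param truth,mean,sd aligned numeric vectors (sd >= 0).
#' @param clip reporting clip (default 5).
#' @return list with \code{z} (raw, possibly infinite) and \code{zClipped}.
#' @export
calibrationZ <- function(truth, mean, sd, clip = 5) {
  if (any(sd < 0)) stop("sd must be non-negative")
  z <- ifelse(sd > 0, (truth - mean) / sd,
              ifelse(truth == mean, 0, sign(truth - mean) * Inf))
  list(z = z, zClipped = pmin(pmax(z, -clip), clip))
}

#' Model resolution matrix
#'
#' \eqn{R = A^+ A}: the linear map from true to naively deconvolved
#' expression, an orthogonal projector onto the row space of the sort
#' matrix. Off-diagonal blocks flag groups of cells whose expression the
#' fraction design blurs together; as linearly independent fractions are
#' added R approaches the identity.
#'
#' @param A a [SortMatrix-class] or numeric matrix.
#' @return symmetric idempotent n x n matrix.
#' @export
resolutionMatrix <- function(A) {
  Am <- .asA(A)
  R <- .pinv(Am) %*% Am
  dimnames(R) <- list(colnames(Am), colnames(Am))
  R
}

#' Expression-weighted resolution matrix
#'
#' Scales column j of the resolution matrix by the expression of cell j
#' (\eqn{R\,\mathrm{diag}(x)}); dark off-diagonal blocks indicate cells
#' whose predicted expression is potentially conflated for this gene.
#'
#' @param R resolution matrix from [resolutionMatrix()].
#' @param x per-cell expression vector.
#' @return n x n matrix.
#' @export
expressionWeightedResolution <- function(R, x) {
  if (length(x) != ncol(R)) stop("x length must match R columns")
  sweep(R, 2L, as.numeric(x), "*")
}

# rowwise Pearson correlation of two genes x cells matrices; NA where either
# row is constant
.rowPearson <- function(P, Q) {
  P <- P - rowMeans(P); Q <- Q - rowMeans(Q)
  num <- rowSums(P * Q)
  den <- sqrt(rowSums(P^2) * rowSums(Q^2))
  ifelse(den > 0, num / den, NA_real_)
}

# deconvolve one gene with any engine; returns list(x=..., failed=logical)
.deconvOne <- function(method, Am, bvec, model, epControl) {
  engine <- switch(method,
    naive = function() naivePseudoinverse(Am, bvec)@estimate,
    constrained = function() constrainedPseudoinverse(Am, bvec)@estimate,
    correlated = function() correlatedPseudoinverse(Am, bvec,
                                                    model)@estimate,
    ep = function() do.call(epDeconvolve,
      c(list(A = Am, b = bvec, damped = FALSE), epControl))@mean,
    ep_damped = function() do.call(epDeconvolve,
      c(list(A = Am, b = bvec, damped = TRUE), epControl))@mean,
    stop("unknown method: ", method))
  tryCatch(list(x = engine(), failed = FALSE),
           error = function(e) list(x = NULL, failed = TRUE,
                                    message = conditionMessage(e)))
}

#' Benchmark deconvolution over fraction counts and noise settings
#'
#' For each fraction count, builds the sort matrix from the first
#' \code{count} reporters of \code{fractionOrder} (plus the all-cells row),
#' simulates per-gene measurements, optionally perturbs the sorting or the
#' measurements, deconvolves with each method and scores every gene by AUC
#' (against truth masks, or against truth binarized at \code{aucThreshold})
#' and Pearson correlation. When a gene in \code{patterns} is itself a sort
#' marker (per \code{geneReporterMap}), that reporter is excluded for that
#' gene and replaced with the next reporter on the list.
#'
#' Sort-matrix perturbations ("flip", "drop") are applied to the matrix used
#' to SIMULATE the measurements, while deconvolution uses the unperturbed
#' matrix -- modelling errors the analyst is unaware of. Measurement noise
#' multiplies each simulated total by an independent N(1, s^2) draw.
#'
#' @param tree a [LineageTree-class].
#' @param patterns an [ExpressionMatrix-class] of ground-truth genes.
#' @param intensities cells x reporters intensity matrix.
#' @param fractionOrder character vector of reporter names, best first (e.g.
#'   from [greedySelect()]).
#' @param counts integer vector of fraction counts to sweep.
#' @param methods subset of c("naive", "constrained", "correlated", "ep",
#'   "ep_damped"); "ep" is undamped and may fail per gene (counted in
#'   \code{nFailed}).
#' @param noise NULL or a list: \code{list(type = "flip"|"drop", nEntries =,
#'   seed =)} or \code{list(type = "measurement", s =, seed =)}.
#' @param model [CorrelationModel-class] for method "correlated".
#' @param geneReporterMap optional named character vector mapping gene names
#'   to the reporter they correspond to (leave-gene-out rule).
#' @param epControl list of arguments passed to [epDeconvolve()].
#' @param aucThreshold binarization threshold for quantitative truth; if
#'   NULL and no truth masks exist, AUC is reported as NA.
#' @param includeNegative add negative-gate rows per reporter.
#' @param dataset label recorded in the output tables.
#' @param seed base seed for the noise draws.
#' @return list with \code{summary} (one row per method x count) and
#'   \code{perGene} (long table of per-gene scores).
#' @export
runBenchmark <- function(tree, patterns, intensities, fractionOrder,
                         counts = c(10L, 20L, 30L, 50L),
                         methods = c("naive", "constrained", "ep_damped"),
                         noise = NULL, model = NULL, geneReporterMap = NULL,
                         epControl = list(), aucThreshold = NULL,
                         includeNegative = FALSE, dataset = "synthetic",
                         seed = 1L) {
  if (max(counts) > length(fractionOrder) -
      as.integer(!is.null(geneReporterMap)))
    stop("fractionOrder must cover max(counts) (plus one spare when the ",
         "leave-gene-out rule is active)")
  X <- exprValues(patterns)
  TM <- truthMask(patterns)
  genes <- rownames(X)
  perGene <- list()
  for (count in counts) {
    baseReporters <- fractionOrder[seq_len(count)]
    Afull <- buildSortMatrix(intensities, reporters = baseReporters,
                             includeNegative = includeNegative,
                             includeAll = TRUE, tree = tree)
    for (mth in methods) {
      for (g in seq_len(nrow(X))) {
        reps <- baseReporters
        if (!is.null(geneReporterMap) && genes[g] %in% names(geneReporterMap)) {
          marker <- geneReporterMap[[genes[g]]]
          if (marker %in% reps) {
            spare <- setdiff(fractionOrder, reps)
            reps <- c(setdiff(reps, marker), spare[1L])
          }
        }
        Aobj <- if (identical(reps, baseReporters)) Afull else
          buildSortMatrix(intensities, reporters = reps,
                          includeNegative = includeNegative,
                          includeAll = TRUE, tree = tree)
        Asim <- Aobj
        if (!is.null(noise) && noise$type %in% c("flip", "drop")) {
          pfun <- if (noise$type == "flip") perturbFlipLineageEntries else
            perturbDropCells
          Asim <- pfun(Aobj, tree, noise$nEntries,
                       seed = (noise$seed %||% seed) + g)$A
        }
        bmat <- measurementValues(simulateMeasurements(Asim, X[g, ]))
        if (!is.null(noise) && noise$type == "measurement") {
          bmat <- measurementValues(perturbMeasurementNoise(
            bmat, noise$s, seed = (noise$seed %||% seed) + g))
        }
        fit <- .deconvOne(mth, sortValues(Aobj), bmat[1L, ], model,
                          epControl)
        if (fit$failed) {
          perGene[[length(perGene) + 1L]] <- data.frame(
            dataset = dataset, method = mth, n_fractions = count,
            gene = genes[g], auc = NA_real_, pearson = NA_real_,
            failed = TRUE, stringsAsFactors = FALSE)
          next
        }
        truthv <- X[g, ]
        auc <- NA_real_
        if (!is.null(TM)) {
          auc <- tryCatch(rocAuc(fit$x, TM[g, ]), error = function(e)
            NA_real_)
        } else if (!is.null(aucThreshold)) {
          auc <- tryCatch(rocAuc(fit$x, truthv > aucThreshold),
                          error = function(e) NA_real_)
        }
        pear <- tryCatch(pearsonAccuracy(fit$x, truthv),
                         error = function(e) NA_real_)
        perGene[[length(perGene) + 1L]] <- data.frame(
          dataset = dataset, method = mth, n_fractions = count,
          gene = genes[g], auc = auc, pearson = pear, failed = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  perGene <- do.call(rbind, perGene)
  agg <- function(df) data.frame(
    dataset = df$dataset[1L], method = df$method[1L],
    n_fractions = df$n_fractions[1L],
    noise = if (is.null(noise)) "none" else
      paste0(noise$type, "=", noise$nEntries %||% noise$s),
    mean_auc = mean(df$auc[!df$failed], na.rm = TRUE),
    mean_pearson = mean(df$pearson[!df$failed], na.rm = TRUE),
    n_failed = sum(df$failed), n_genes = nrow(df),
    stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(
    split(perGene, list(perGene$method, perGene$n_fractions), drop = TRUE),
    agg))
  summary <- summary[order(summary$method, summary$n_fractions), ]
  rownames(summary) <- NULL
  list(summary = summary, perGene = perGene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired significance tests between deconvolution methods
#'
#' Paired t-tests on per-gene scores between every pair of methods within
#' each fraction count, with Bonferroni correction across the number of
#' comparisons actually run (or a fixed \code{nTests}).
#'
#' @param perGene the \code{perGene} table from [runBenchmark()].
#' @param metric "auc" or "pearson".
#' @param alpha significance level before correction (default 0.05).
#' @param nTests Bonferroni denominator; default the number of comparisons.
#' @return data.frame with one row per (count, method pair): mean
#'   difference, raw and corrected p-value, significance flag.
#' @export
pairedMethodComparison <- function(perGene, metric = c("auc", "pearson"),
                                   alpha = 0.05, nTests = NULL) {
  metric <- match.arg(metric)
  out <- list()
  for (count in sort(unique(perGene$n_fractions))) {
    sub <- perGene[perGene$n_fractions == count & !perGene$failed, ]
    wide <- split(sub, sub$method)
    ms <- names(wide)
    if (length(ms) < 2L) next
    for (i in seq_len(length(ms) - 1L)) for (j in (i + 1L):length(ms)) {
      a <- wide[[ms[i]]]; bb <- wide[[ms[j]]]
      common <- intersect(a$gene, bb$gene)
      va <- a[[metric]][match(common, a$gene)]
      vb <- bb[[metric]][match(common, bb$gene)]
      ok <- is.finite(va) & is.finite(vb)
      if (sum(ok) < 3L) next
      tt <- tryCatch(stats::t.test(va[ok], vb[ok], paired = TRUE),
                     error = function(e) NULL)
      if (is.null(tt)) next
      out[[length(out) + 1L]] <- data.frame(
        n_fractions = count, method1 = ms[i], method2 = ms[j],
        mean_diff = mean(va[ok] - vb[ok]), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  denom <- nTests %||% nrow(res)
  res$p_bonferroni <- pmin(res$p * denom, 1)
  res$significant <- res$p_bonferroni < alpha
  res
}
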