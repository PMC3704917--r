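---
title: "Deconvolving per-cell expression from overlapping sorted fractions"
author: "lindeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving per-cell expression from overlapping sorted fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lindeconv)
```

## The inverse problem

In organisms with an invariant cell lineage — the *C. elegans* embryo being
the canonical case, with 671 terminal cells and 1,341 cells in total — a
cell's position in the pedigree fully determines its identity. Fluorescent
reporter strains whose expressing cells have been mapped by lineage tracing
can then be used as FACS sort markers: sorting cells positive (or negative)
for a reporter yields a *fraction* whose exact cellular composition is
known, and a single RNA-seq measurement of that fraction gives, for every
gene, the summed expression of its constituent cells.

For one gene, let $x \in \mathbb{R}^n_{\ge 0}$ be its unknown expression
across the $n$ cells and $b \in \mathbb{R}^m$ the measured totals in $m$
fractions. The sort matrix $A \in [0,1]^{m \times n}$ holds the membership
probability of cell $j$ in fraction $i$, giving the underdetermined
non-negative linear system

$$ A x = b, \qquad x \ge 0 . $$

Because $m \ll n$, the solutions form a convex polytope
$\{x \ge 0 : Ax = b\}$; its size expresses how much the design leaves
undetermined. The package provides point estimators, posterior
approximations over the polytope, design tools for choosing fractions, and
the synthetic generators needed to study all of these without any external
data.

## Sort matrix construction

Reporter on/off calls are probabilistic: intensities are modelled as an
equal-prior mixture of two Gaussians, off $\mathcal N(0, 1000^2)$ and on
$\mathcal N(2000, 1000^2)$ (arbitrary background-subtracted units). With
equal variances the posterior on-probability is logistic in the intensity
(`intensityToOnProbability()`), so matrix entries fall in $[0,1]$ and are
used as-is, never rounded. Each chosen reporter contributes a positive-gate
row; a negative-gate row ($1-p$) is optional, and an all-cells row of ones
(an unsorted sample) is included by default — it both anchors the total
expression and bounds the feasible polytope.

## Point estimators

* **Naive pseudoinverse** (`naivePseudoinverse()`): $\hat x = \max(A^+ b,
  0)$ with $A^+$ the Moore–Penrose pseudoinverse (SVD, relative
  singular-value cutoff $10^{-10}\sigma_{max}$). Truncation generally
  breaks the equality, which the `feasible` flag reports.
* **Constrained pseudoinverse** (`constrainedPseudoinverse()`): the
  minimum-2-norm point of $\{x \ge 0: Ax = b\}$ — the maximum-likelihood
  point under a standard normal prior restricted to the constraints. The
  equality is eliminated with an orthonormal null-space basis, reducing the
  problem to least-distance programming, solved via a single non-negative
  least-squares call (Lawson–Hanson).
* **Correlation-weighted pseudoinverse** (`correlatedPseudoinverse()`):
  minimizes $x^\top \Sigma^{-1} x$ under the same constraints, where
  $\Sigma$ is a cell–cell correlation estimated across genes and shrunk as
  $(1-\lambda)\hat R + \lambda I$ with $\lambda = 0.05$
  (`shrunkenCorrelation()`); the Cholesky substitution $x = Ly$ turns this
  into the same least-distance program.

When the equality is unsatisfiable under $x \ge 0$ (typical once
measurements carry noise), both constrained variants fall back to the
non-negative least-squares residual minimizer and, among all minimizers,
return the least-norm one (the minimizer set is exactly
$\{x \ge 0 : Ax = \hat b\}$ with $\hat b$ the fitted value, so a second
least-distance solve finishes the job). This makes the estimators total;
`feasible = FALSE` marks the fallback.

## Expectation propagation

`epDeconvolve()` approximates the uniform distribution over the feasible
polytope with a multivariate Gaussian, yielding a mean and a covariance —
an intrinsic uncertainty estimate. One univariate Gaussian site per cell
represents the $x_i \ge 0$ indicator; parallel sweeps update all sites by
truncated-normal moment matching on the cavity (computed from the
start-of-sweep posterior), and the posterior is conditioned on $Ax = b$ by
exact Gaussian conditioning with jitter $10^{-8}$ times the trace scale.

Numerical choices, all tunable:

* **Working scale.** "Relative expression": $b$ is divided by the total
  expression (the all-cells measurement when present, else
  $\sum b / \mathrm{rank}(A)$); results are rescaled afterwards. There is
  no canonical convention for this normalization, so it is the package's
  own choice, made so the remaining constants have stable meanings.
* **Prior.** $\mathcal N(0, \tau I)$ with $\tau = 100 \times$ total (i.e.
  100 on the relative scale) — weak, but it keeps early iterations bounded.
* **Offset.** $10^{-3}$ is added to every cell's relative expression
  (shifting $b$ by $10^{-3} A\mathbf 1$) so the polytope has strict
  interior, and subtracted from the returned mean.
* **Damping.** The step size starts at 1; in damped mode any numerical
  failure (negative or collapsed cavity variance, non-finite update) halves
  the step and retries from the last valid state, so a result is always
  returned and `converged` reports the truth. Undamped mode raises an error
  naming the sweep instead — useful for counting hard instances. Cavity
  variances are floored at $10^{-12}$.
* **Convergence.** Maximum natural-parameter change below $10^{-6}$
  (default), at most 200 sweeps.

`epGroupSummary()` aggregates the posterior over a cell mask (a sublineage,
say): the group total has mean $\sum_{i \in M} \mu_i$ and variance
$\mathbf 1^\top \Sigma_M \mathbf 1$, so negative covariances narrow group
intervals — group predictions do not commit to *which* cell inside the
group expresses, and are correspondingly tighter.

## Polytope sampling

`sampleFeasible()` draws uniform samples from the polytope by
random-direction (hit-and-run) MCMC, implemented in C++: each step draws a
direction uniformly in the null space of $A$ (SVD basis, computed once),
finds the feasible segment, and jumps to a uniform point on it. Cells whose
constrained-pseudoinverse estimate is below $10^{-8}$ of the maximum are
omitted and pinned at zero — on boundary-heavy polytopes the chain
otherwise cannot move. Defaults mirror the reference protocol ($10^7$
burn-in, $10^7$ iterations, thinning 1000); the examples and tests use
$10^4$–$10^5$-scale chains, which already reproduce Dirichlet analytics on
simplices to two decimals. With $\ge 2$ chains, per-coordinate Gelman–Rubin
$\hat R$ (`potentialScaleReduction()`, with the $(n-1)/n$ correction) is
reported; each chain starts from a distinct point obtained by a short
seeded pre-walk.

## Confidence and design tools

The model resolution matrix $R = A^+ A$ (`resolutionMatrix()`) is the
orthogonal projector describing which cells the design blurs together;
it approaches the identity as independent fractions are added, and
`expressionWeightedResolution()` highlights the blocks that matter for a
given gene. `calibrationZ()` scores uncertainty estimates by scaling the
truth to the predicted mean and standard deviation (reporting clipped at
$\pm 5$).

`greedySelect()` orders candidate reporters by iteratively adding the one
that maximizes the mean Pearson correlation of deconvolved one-lineage
patterns, using the naive pseudoinverse as the (cheap) inner engine and
the all-cells fraction as a standing baseline. Ties break by input order;
undefined correlations count as zero. On bisection-style candidate sets
$\lceil \log_2 n \rceil$ fractions suffice to localize single cells, which
the greedy trace recovers.

## Synthetic data: what it emulates, and what it does not

* `generateSyntheticLineage()` builds a mirrored binary pedigree — two
  identical-topology subtrees under one root — reflecting the left-right
  symmetry of real lineages; `depthJitter` randomizes division depths.
* `simulateLineagePatterns()` draws one gene per sublineage (or symmetric
  sublineage pair) with at least `minCells = 5` cells: on-cells
  $\mathcal N(10, 11)$, off-cells $\mathcal N(0, 1)$, negatives truncated
  to zero. (Some descriptions of this design transpose the two parameter
  sets, making "off" brighter than "on", which contradicts every AUC
  convention downstream; `literalParameterization = TRUE` reproduces that
  transposed variant.) A
  gamma variant uses Gamma(1, 1) off-cells with a user grid of on-cell
  shape/scale.
* `simulateCorrelatedPatterns()` draws truncated multivariate normals with
  a shrunken lineage-correlated covariance (200 genes by default).
* `simulateReporterIntensities()` emulates reporter strains. Real reporters
  label broad lineage territories, so by default each reporter is on in a
  union of random sublineages grown to a coverage target drawn
  U(0.15, 0.5); `coverage = NULL` gives single-sublineage reporters.
  `reporterExpressionPatterns()` turns the reporter masks themselves into
  an on/off benchmark — the synthetic analogue of using measured reporter
  patterns as evaluation genes, with the leave-gene-out rule excluding each
  gene's own marker during its deconvolution.

None of these emulate RNA-seq count noise (negative binomial dispersion,
amplification bias), temporal dynamics, or the irregular topology of a real
pedigree; passing benchmarks on them demonstrates the estimators' geometry,
not performance on real sequencing data.

## Benchmark harness and study sizes

`runBenchmark()` sweeps fraction counts and noise settings: for each count
it takes the first $k$ reporters of a (greedy) order, simulates per-gene
measurements, optionally perturbs, deconvolves with each method and scores
AUC (midrank Mann–Whitney) against truth masks plus Pearson correlation;
EP failures in undamped mode are counted, not fatal. The three noise models
follow the error simulations of the underlying study: *flip* (a random
sublineage within one fraction has entries $\alpha \to 1-\alpha$; drawn
repeatedly until the entry budget is met), *drop* (random sublineages
zeroed across all fractions), and multiplicative measurement noise
$\mathcal N(1, s^2)$ clamped at zero. Flip and drop perturb the matrix used
to *simulate* measurements while deconvolution uses the clean matrix —
errors the analyst is unaware of. Perturbations are redrawn per gene, and
lineages are drawn uniformly from all sublineages, so occasional large
blocks dominate single draws; averaging across genes is essential.
`pairedMethodComparison()` runs Bonferroni-corrected paired t-tests between
methods.

The package's own reference study (used throughout the test suite) runs on
a 255-cell mirrored lineage with 60 broad candidate reporters, greedy
ordering over the 63 one-lineage patterns, and fraction counts
{10, 20, 30, 50}; at 30 fractions both EP and the constrained pseudoinverse
exceed 0.97 mean AUC, with clear diminishing returns past 30. These sizes
were chosen so the whole study re-runs in minutes on one core while staying
well inside the regime where the estimators differ meaningfully.

## Known limitations

* **Inconsistent measurements.** Multiplicative noise on fraction totals
  usually makes $\{x \ge 0 : Ax = b\}$ empty (in the reference study, for
  essentially every gene at $s = 0.5$). EP as implemented still conditions
  on the equality exactly, and the pseudoinverse fallback projects onto
  the feasible cone; both lose substantial AUC, and in this regime the
  naive pseudoinverse is empirically the most robust of the three — the
  opposite of the ordering reported on real measured patterns in the
  literature this package builds on. A noise-aware likelihood (replacing
  exact conditioning with a Gaussian observation model) would be the
  principled extension and is deliberately out of scope here.
* **Calibration.** On synthetic on/off benchmarks, EP's per-cell z-scores
  are approximately standard normal (sd ≈ 1.1) rather than strongly
  conservative: truncated truth vectors sit on the polytope boundary, a
  harder case than uniform-typical points. EP marginal standard deviations
  do dominate sampling standard deviations essentially everywhere, as
  expected.
* **Counting conventions.** Sublineage size thresholds count all cells of
  the rooted subtree by default (`count = "all"`), since the sort matrix
  carries one column per cell; a terminal-only convention is available, and
  with real lineage tables either can be used to match published sublineage
  tallies.
* The hit-and-run sampler requires a bounded polytope (an all-cells
  fraction guarantees this); moves along unbounded directions are skipped.
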