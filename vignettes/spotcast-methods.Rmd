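---
title: "Mapping cell annotations onto spatial transcriptomics with SpotCast"
author: "SpotCast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cell annotations onto spatial transcriptomics with SpotCast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpotCast)
```

## The problem

Single-cell RNA sequencing resolves individual cells and a large part of
the transcriptome but discards spatial context; spatially resolved
transcriptomics (SRT) keeps the coordinates but trades off resolution
against gene coverage. Imaging platforms (MERFISH, osmFISH, ISS, Xenium)
measure a few hundred genes at single-cell resolution; sequencing
platforms (Visium, Spatial Transcriptomics) measure the whole
transcriptome averaged over multicell capture spots. SpotCast transfers
annotations — cell types, states, region labels, or the expression of
genes the spatial panel does not measure — from an annotated single-cell
reference onto SRT spots. For single-cell resolution data the output is
a membership probability vector per spot; for multicell data it is a
vector of absolute population abundances per spot, whose sum estimates
the number of cells in the spot.

## The model

Let $X^R$ be the centroid expression of the reference (sub-)populations
$c \in C'$ and $X^S$ the spot expression, both over the shared gene set
$G$. The decision variable is a nonnegative transfer matrix $Y$ with
$Y_{c,i}$ the abundance of population $c$ at spot $i$, constrained by
$1 \le \sum_c Y_{c,i} \le n_i$ where $n_i$ is the spot capacity (1 at
single-cell resolution). Five objectives are combined:

* **Spot matching** — each spot's profile should match the profile
  transferred to it, $d_{\cos}(X^S_{i,:}, \sum_c Y_{c,i} X^R_{c,:})$,
  where $d_{\cos}(a,b) = \sqrt{1 - \cos(a,b)}$. The square root makes
  this a true metric on rays of the positive orthant, and scale
  invariance makes the model indifferent to platform sensitivity and to
  spot or population size. A sparsity parameter $\theta \in [0,1]$
  interpolates between this composite form and its linear-in-$Y$
  counterpart $\frac{1}{\bar n_i}\sum_c Y_{c,i}\, d_{\cos}(X^S_{i,:},
  X^R_{c,:})$; the two coincide on one-population columns, and because
  linear objectives favour corner points, larger $\theta$ yields purer
  spots.
* **Population matching** — each reference centroid should match the
  expression the map assigns to that population in space (weight
  $\lambda_C$).
* **Gene-map matching** — each shared gene's spatial map should match
  the transferred map (weight $\lambda_G$).
* **Spatial smoothing** — adjacent spots with similar expression
  (over the *full* spatial panel, including genes the reference lacks)
  should have similar compositions, penalised by a weighted base-2
  Jensen–Shannon divergence between raw composition columns (weight
  $\lambda_S$). The pair set is local and data-driven; no global
  spatial correlation is assumed.
* **Abundance prior** — optionally, total population masses should
  match expected abundances $r$ (weight $\lambda_A$), compared with the
  same Jensen–Shannon divergence. This is defined at the population
  level, not the sub-cluster level, because priors are typically known
  for populations.

Within-population heterogeneity is handled before fitting: each
population is split into up to $\kappa$ sub-clusters by k-means on all
reference genes (10 restarts, seeded), sub-clusters under 1% of the
population are dropped as outliers, and the fitted sub-cluster map is
summed back to populations afterwards.

## Parameters and their defaults

All hyperparameters are inferred from the data so that the active
objectives contribute on comparable scales; every one can be
overridden.

| parameter | default | meaning |
|---|---|---|
| $n$ | 1 (high), 20 (Visium), 200 (ST), else $N/\lvert I\rvert$ | spot capacity, cells |
| $\theta$ | 0.6 (high), 0.4 (low) | sparsity of compositions |
| $\lambda_C$ | $0.5\lvert I\rvert/\lvert C'\rvert$ (high), $0.6\lvert I\rvert/\lvert C'\rvert$ (low) | population term |
| $\lambda_G$ | $1.25\lvert I\rvert/\lvert G\rvert$ (high), $1.5\lvert I\rvert/\lvert G\rvert$ (low) | gene-map term |
| $\lambda_S$ | $0.5\lvert I\rvert/\lvert P\rvert$ (high), $0.4\lvert I\rvert/(n\lvert P\rvert)$ (low) | spatial term |
| $\lambda_A$ | $1/n$ with a prior, else 0 | abundance term |
| $\kappa$ | 10 | sub-clusters per population |
| $\bar d$ | 90th percentile of pooled 8-NN distances | adjacency radius |
| $\bar w$ | $\max(0.6,$ largest cutoff keeping $\lvert P\rvert \le \lvert I\rvert)$ | similarity cutoff |

The capacity fallback $N/\lvert I \rvert$ needs a user-supplied total
cell count $N$; SpotCast deliberately ships no estimator for $N$, so
multicell data without a platform, capacity, or total count is an
error rather than a guess. The distance percentile uses
`stats::quantile` type 7 (linear interpolation between order
statistics) — one fixed convention for reproducibility across
platforms. Ties at the similarity cutoff are all kept, since the
cutoff is defined on the value, not the count, so the pair set can
slightly exceed $\lvert I \rvert$.

Expression is consumed as provided: the model works with counts and
continuous intensities alike and applies no internal normalisation
(`scaleTotals` exposes an optional per-row total-count scaling; gene
matching is by exact identifier after whitespace stripping, with no
case folding — silent mismatches are worse than explicit errors).

## Optimisation

The weighted objective is minimised by a Frank–Wolfe
conditional-gradient loop. Its linearisation splits into one problem
per spot — minimise $\langle y, \delta_i\rangle$ over
$\{y \ge 0,\ 1 \le \sum y \le n_i\}$ — whose solution is closed-form:
a one-hot column on the category with the smallest coefficient, scaled
to $n_i$ when that coefficient is negative and to 1 otherwise (ties go
to the smallest index, for determinism). Iterates are convex
combinations of feasible points, so the capacity constraints hold
exactly at every iteration. The start point is the uniform column
$Y_{c,i} = 1/\lvert C' \rvert$, an unbiased interior point.

Numerical choices:

* **Gradient smoothing.** $d_{\cos}$ has unbounded derivative as
  $\cos \to 1$; for differentiation the $1-\cos$ factor is clamped at
  $10^{-9}$, and Jensen–Shannon log arguments are floored at
  $10^{-12}$. The reported objective is never smoothed, and the effect
  vanishes as the clamps go to zero; at random interior points the
  analytic gradient matches central finite differences of the exact
  objective to better than $10^{-5}$ relative error.
* **Step size.** Armijo backtracking from $\gamma = 1$, which keeps
  the trace monotone. Near perfectly matched profiles the smoothed
  gradient overstates the achievable decrease and no step can clear
  the Armijo bar; the solver then takes the largest step that still
  plainly decreases the objective instead of stopping, a monotone form
  of the usual diminishing-step fallback.
* **Stopping.** Relative objective change below $10^{-6}$, a vanishing
  duality gap, or 300 iterations. Conditional-gradient convergence is
  sublinear, and we found that hard labels stabilise long before the
  column masses do: with a looser $10^{-5}$ tolerance the estimated
  spot sizes were still far from their settled values, while at
  $10^{-6}$ the size estimates agree closely with the truth on the
  synthetic benchmarks. Hence the deeper default.
* **Degenerate inputs.** An all-zero vector is assigned cosine
  distance 1 to any nonzero vector and 0 to another all-zero vector —
  bounded and continuous-in-the-limit rather than NaN. All-zero spots
  join no spatial pair (their cosine similarity is undefined) and are
  reported with a warning.

With all $\lambda = 0$, $\theta = 1$ and $n = 1$ the model is linear,
the first atom is already optimal, and the fit reduces exactly to
nearest-centroid assignment under $d_{\cos}$ in one iteration — a
useful exactness check that the test suite exercises.

## The synthetic benchmark generator

`simulationSpec()` and its companions generate the study conditions the
package is validated under: 10 populations, 100 genes with 5 markers
per population elevated 10-fold over a shared baseline, 100 reference
cells per population, 2025 single-cell spots placed uniformly in a
square of side 45 with population labels forming contiguous Voronoi
regions, Poisson counts around the population programs, optional
within-population subtypes (to exercise sub-clustering), multiplicative
uniform noise $1 + \beta$, $\beta \sim U(-\varphi, \varphi)$ with
$\varphi \in \{0, 0.25, 0.5\}$ the conventional settings, and pooling
into square tiles of side 3.2 — chosen so tiles hold roughly 10 cells,
a Visium-like density, giving about 200 nonempty tiles. Cells are
placed uniformly at random rather than on a lattice so that tile cell
counts vary as they do in tissue (a lattice would make every interior
tile identical, leaving spot-size recovery untestable); a lattice mode
exists for constructing regular fixtures. Tiles take the tile-centre
coordinate and empty tiles are dropped.

Poisson emission is deliberately the simplest model that exercises all
code paths; a fold-change knob controls subtype separation, but there
is no attempt to emulate platform error structure (dropout,
segmentation errors, spot bleed). Passing the synthetic benchmarks
therefore shows that the estimator recovers planted structure under
clean generative assumptions — not that it is robust to every artefact
of real tissue.

## Evaluation metrics

For labelled single-cell resolution truth: classification accuracy;
the Brier score $\lvert I\rvert^{-1}\sum_{i,c}(Y_{c,i} - P_{c,i})^2$
(a strictly proper score of probability calibration); and the spatial
Jensen–Shannon divergence, the mean base-2 JS divergence between
predicted compositions and a Gaussian-kernel smoothing of the one-hot
truth ($K_{i,j} = \exp(-\lVert x_i - x_j\rVert^2 / 2\sigma^2)$,
self-term included so columns stay probability vectors; $\sigma$
defaults to $0.5\bar d$). For multicell truth: the per-spot base-2 JS
divergence between estimated and true relative compositions, and the
Pearson correlation between estimated and true spot sizes.

## Design choices on genuinely open points

* **Jensen–Shannon on raw columns.** The spatial and abundance terms
  apply JS to unnormalised nonnegative vectors. This matches the bound
  $0 \le d_S \le n\lvert P\rvert$ that motivates the default
  $\lambda_S$, and lets the spatial term see size differences between
  neighbouring spots. A normalise-first mode exists but is off by
  default.
* **$\bar n_i$ in the sparsity term** is fixed to the capacity $n_i$.
* **$\lambda_C$ uses the number of rows actually optimised** (the
  sub-cluster count $\lvert C'\rvert$), since that is what bounds the
  population term after refinement.
* **k-means for sub-clustering.** Any unsupervised partition would do;
  k-means with fixed seed and 10 restarts is fast and deterministic.
  Singleton sub-clusters (one per cell) are supported via large
  $\kappa$ but are not the default — transferring individual cells is
  expensive and prone to over-fitting.
* **Feature transfer weighting.** Predicted features are
  $\hat Y^\top F$ with $\hat Y$ column-normalised at single-cell
  resolution (columns are probabilities) and raw at multicell
  resolution (features should scale with spot size); both behaviours
  are switchable.
* **Duplicate coordinates** contribute their true zero distances to
  the 8-NN pool of $\bar d$.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from
code: unit fixtures of a few dozen spots; property checks on $10^4$
random triples (metric axioms), $10^3$ random gradients (subproblem
optimality against vertex enumeration), and 100 random instances
(finite-difference gradient agreement); and recovery runs at the
benchmark scale above (2025 spots, pooled to ~200 tiles, fits at
capacities 10 and 20, 20 held-out genes aggregated on a 10 × 10 grid).

## Known limitations

* The generator's Poisson emission and block-marker programs are an
  idealisation; real references carry batch effects, ambient RNA and
  dropout the model never sees in testing.
* The total-cell-count capacity fallback requires the user to supply
  $N$; there is no built-in estimator.
* The objective is non-convex in $Y$ (the spatial and abundance terms
  are convex, the cosine terms only quasi-convex), so Frank–Wolfe
  finds a stationary point, not a certified global optimum; the
  uniform start and the data-driven weights make the solution
  deterministic and empirically stable.
* Alternative scale-invariant divergences (LeCam and other symmetric
  f-divergences) would slot into the same framework but are not
  implemented.

## A minimal session

```{r example, eval = FALSE}
spec <- simulationSpec(seed = 1)
ref <- makeReference(spec)
hs <- makeHighresSpatial(spec)

fit <- fitTransfer(ref, hs$spatial, mode = "high")
mean(hardLabels(fit) == as.character(hs$truth@labels))

lr <- poolToLowres(hs$spatial, hs$truth, spec$tileLength)
fitL <- fitTransfer(ref, lr$spatial, mode = "low", capacity = 10)
cor(spotSizes(fitL), lr$truth@cellCount)
```
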