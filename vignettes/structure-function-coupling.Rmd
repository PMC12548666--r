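---
title: "Methods: regularized partial correlation and cross-modularity for structure-function coupling"
author: "sfcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized partial correlation and cross-modularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcoupling)
```

## The problem

Functional connectivity (FC) between brain regions is usually summarized by
the correlation matrix **C** of region-wise activity time series, and less
often by the partial correlation — the standardized precision (inverse
correlation) matrix, here written `Jt`. Under a Gaussian approximation the
partial correlation keeps only *direct* conditional dependencies between
regions, which makes it the more natural counterpart of anatomical
(structural) connectivity (SC). Its drawback is statistical: when the
regions-to-timepoints ratio `q = N/T` is not small, the sample correlation
`E = X X^T / T` is a noisy estimate and its inverse is much worse.
`sfcoupling` implements the full analysis that turns this observation into a
testable pipeline:

1. regularized estimation of `C` and `Jt` by six noise-cleaning algorithms,
   with the strength selected by validation likelihood;
2. sparsification of the absolute-valued connectivity at the percolation
   threshold;
3. comparison of the functional and structural graphs across their whole
   hierarchy of nested partitions with the cross-modularity statistic; and
4. population-level characterization: bootstrap stability of the population
   partition and disease gene-set Z-scores over modules.

Because the package is validated on synthetic data, the cohort generator is
a first-class module: it plants the ground truth that every downstream claim
is measured against.

## Estimators

All estimators operate on the sample correlation `E` of a row-standardized
panel (each region demeaned and scaled so `E` has exact unit diagonal).

* **IS / GS (linear shrinkage)** — `C(a) = (1 - a) E + a T` with the
  identity target (IS) or the across-subject mean sample correlation (GS).
  `a = 0` is the raw estimator, `a = 1` the fully biased one.
* **PCA (eigenvalue clipping)** — keep the `p` leading sample eigenvalues,
  replace the bulk by its mean; eigenvectors and trace unchanged. The
  strength is parametrized as `alpha = (N - p)/N`.
* **cautPCA** — floor the spectrum at the `p`-th eigenvalue and rescale so
  the trace equals `N`; a cautious variant of clipping.
* **GLASSO** — l1-penalized Gaussian maximum likelihood for the precision
  matrix, implemented by block coordinate descent with an off-diagonal-only
  penalty; it returns a genuinely sparse precision and its inverse. The
  duality gap `tr(EJ) + penalty * |J|_1,off - N` is driven below `1e-5`
  (default), with at most 500 sweeps.
* **ORIE (rotationally invariant eigenvalue cleaning)** — each sample
  eigenvalue is corrected by the squared modulus of `1 - q + q z s(z)`
  evaluated at `z = lambda - i eta`, where `s` is the sample Stieltjes
  transform; eigenvectors are kept and the cleaned spectrum is rescaled to
  preserve the trace (without that step a flat spectrum would not map to
  itself). The default `eta = N^{-1/2}`; because that can be too coarse at
  moderate `N`, `eta` is cross-validated like every other strength.

**Strength selection.** The time axis is split into 5 contiguous blocks
(contiguity respects temporal autocorrelation); for each candidate strength
the estimator is fitted on the training blocks and scored by the mean
Gaussian log-likelihood of the validation block (`1/T_val` sample
correlation, consistently with the `1/T` convention used throughout). Ties
are broken toward the stronger regularization, since likelihood plateaus
favor the stabler estimator. Default grids: 21 evenly spaced values in
`[0, 1]` for IS/GS; every integer `p` for PCA/cautPCA; 16 log-spaced
penalties in `[1e-3, 1]` for GLASSO; `N^{-1/2}` plus 8 log-spaced values in
`[1e-4, 1e-1]` for ORIE.

**Partial correlation sign convention.** `Jt_ij = J_ij / sqrt(J_ii J_jj)` is
implemented exactly as written, without the conventional minus sign; all
downstream stages use absolute values, so results are unaffected. The
`signed = TRUE` flag gives the conventional convention for users who want
interpretable signs.

**GS target.** The group target is the mean of the *raw* sample
correlations of all subjects, including the focal one. In a large cohort
the focal subject's contribution to the target is negligible; in a small
one it lets the validation fold leak into the target, and the selected
strength then saturates at 1 (every subject collapses onto the group
matrix). `subject_sweep(gs_loo = TRUE)` therefore substitutes the
leave-one-out group mean per subject, which restores an interior optimum;
the package's experiment drivers use it, while direct calls default to the
all-subject target.

## Graphs

Adjacency matrices are the element-wise absolute values with zeroed
diagonal. The percolation threshold `tau*` is the largest cutoff at which
the surviving graph is still one connected component; it is computed as the
bottleneck (minimum weight) of a maximum spanning tree, which is exact and
independent of any edge ordering. Edges of equal weight are kept or removed
together, so the output is a deterministic function of the weight multiset.
Fixed-density cuts (`threshold_to_density`) keep the top-k edges, keep ties
at the cut, and do not enforce connectivity.

## Hierarchy comparison

Each sparse graph is clustered agglomeratively on the condensed distance
`d_ij = exp(-A_ij)` with weighted-average (WPGMA) linkage; cutting one
dendrogram at every `m` guarantees nested partitions. (A cosine-distance
alternative on adjacency rows is available behind `features = "cosine"` for
sensitivity checks; the condensed-distance recipe is the default because a
precomputed condensed distance makes any declared point-metric inert.)

For each `m` the package computes the Newman modularity `Q` of each graph
under its own partition — on the *binarized* graph, and without any
modularity maximization: `Q` is simply evaluated at every level of the
dendrogram — and the adjusted normalized mutual information `nu` between
the two partitions, with the expectation term taken under the
permutation (hypergeometric) model and max-entropy normalization. The
cross-modularity is the geometric mean

  chi(m) = (Q_F(m) * Q_S(m) * nu(m))^(1/3),

with each factor floored at zero so that `chi = 0` whenever any factor is
non-positive — consistent with both `Q` and `nu` vanishing for random or
unrelated partitions, and avoiding cube roots of negative products. The
default hierarchy depth is `m_max = min(50, N - 1)` (the package's
experiments use 20 at `N = 60`).

The spectral distance between two adjacency matrices is the sum of absolute
differences of their descending-sorted eigenvalues (sorted descending so
the quantity is a metric on spectra). Structural weights, which live on a
streamline-count scale, are mapped through `2 * atan(w) / pi` into `[0, 1)`
before spectra are compared with functional ones.

## Synthetic cohorts

The generator plants a modular Gaussian graphical model: off-diagonal
precision entries are negative on edges sampled within (and more densely
within sub-) modules, positive definiteness is enforced by diagonal loading
and the precision is normalized to unit diagonal. Time series are drawn
from the implied covariance, optionally mixed through a stationary AR(1)
recursion (`x_t = a x_{t-1} + sqrt(1 - a^2) eps_t`), then standardized. The
structural matrix shares the precision support, with heavy-tailed
(lognormal) positive weights emulating streamline counts, a rewired edge
fraction emulating structure-function mismatch, and a minimum-weight chain
added only if the graph would otherwise be disconnected. Per-subject
variation multiplies nonzero weights by lognormal jitter. The transcriptome
is unit Gaussian noise with a planted `+3`-sd mean shift of each disease
gene set inside its target module.

Default conditions (chosen once as a realistic desk-scale analogue and then
left alone): `N = 60` regions in 6 coarse modules each split in two
(`intra_p = 0.45`, `sub_p = 0.6`, `inter_p = 0.01`), precision edge
magnitudes `U(0.15, 0.35)`, condition-number target 100, rewiring fraction
0.1, structural lognormal `meanlog = 3, sdlog = 0.8`, subject jitter 0.1,
`T = 200` so `q = 0.3` — matching the regions-to-timepoints ratio of typical
resting-state cohorts. The condition-number target matters: with a very
ill-conditioned planted precision the covariance develops one dominant
global mode, all correlations saturate and the percolation graph becomes
near-complete, which no empirical correlation matrix resembles. The
coarse/sub-module edge densities were chosen so that the coarse partition is
the dominant modular scale of the true graphs themselves; with weakly knit
modules the dendrogram's natural scale drifts away from the planted count
and a recovery experiment would measure nothing.

What the generator does *not* emulate: hemodynamics, spatial geometry of
regions, non-Gaussian marginals, and global signal confounds. Passing the
recovery experiments therefore shows that the pipeline recovers planted
modular structure under Gaussian assumptions at realistic `q`, not that it
is robust to all features of real recordings.

## Recovery experiments

`experiment_*` drivers regenerate cohorts under the default conditions and
measure one contrast each:

* **headline** — per-subject peak cross-modularity of `Jt`-based FC against
  SC exceeds that of `C`-based FC (GS regularization, likelihood-selected
  strength, one-sided Mann-Whitney).
* **support recovery** — cohort-mean AUC of edge ranking against the planted
  precision support, `|Jt|` vs `|C|`, per seed.
* **raw vs regularized** — at `N = 90, T = 120` (`q = 0.75`) the raw inverse
  is a poor coupling estimate and likelihood regularization repairs it
  (paired one-sided rank test over seeds).
* **alpha robustness** — the likelihood-selected strength attains at least
  90% of the coupling achieved by the oracle strength that maximizes
  coupling itself (which peeks at SC). With GS this holds for every subject
  tested; with IS the coupling profile keeps improving beyond the
  likelihood optimum and the fraction drops to roughly 60% — a known
  limitation of the synthetic conditions, noted here because the
  experiment defaults to GS.
* **curve shape** — `chi(m)` rises, attains an interior soft maximum and
  decays; the cohort's representative partition size is the across-subject
  *median* argmax (the per-subject argmax jitters along the plateau and is
  not a stable estimator), and lands within 2 of the planted coarse count.
* **density sweep** — at matched fixed FC densities the `Jt`-based coupling
  stays above the `C`-based one for sparse graphs, so the advantage is not
  a mere density artifact.

## Population stage

The population connectivity is the element-wise median of per-subject
absolute partial correlations at their likelihood-selected strengths. For
bootstrap stability those per-subject matrices are computed once (including
the GS target) and replicates only resample, with replacement, which
matrices enter the median — re-cross-validating inside every replicate
would multiply the cost without changing which quantity is resampled.
Replicates are scored against the reference partition by adjusted NMI;
per-module persistence encodes each module as its in/out indicator and
takes the best-match NMI within each replicate, averaged over replicates.

Disease Z-scores standardize, across modules, the median expression of a
disease's genes over a module's regions (sample standard deviation,
denominator `n - 1`); `|z| > 2` flags over/under-representation. Note that
a standardized vector of length `n` is bounded by `(n - 1)/sqrt(n)`, so
`|z| > 2` is only reachable with at least 6 modules.

## Numerical choices and degenerate inputs

* Non-positive-definite likelihood candidates score `-Inf` rather than
  erroring, so a grid search never aborts.
* Percolation on a disconnected input is an error (the threshold is
  undefined), as is modularity of an edgeless graph.
* Adjusted NMI of two single-module labelings is defined as 1 when the
  partitions coincide and 0 otherwise (zero-entropy guard).
* Constant expression columns yield all-zero Z-scores with a warning;
  diseases with no mapped genes are dropped with a warning.
* All randomness flows from explicit integer seeds; a configuration plus
  seed reproduces every artifact bit-identically.

## I/O and scale

Matrices are exchanged as delimited text (TSV/CSV): panels as plain numeric
matrices, expression tables with a region-id header and gene-id first
column, graphs as 0-based weighted edge lists, partitions as two-column
region/module files. `run_pipeline()` executes the full chain from a
validated configuration (R list or YAML) and writes a JSON manifest
recording versions, the configuration and all artifacts. The package's own
experiments run at `N = 60`, `T = 200`, cohorts of 6-20 subjects and
`m_max = 20`, sizes chosen so the full suite and the acceptance script each
complete in about a minute on one core while keeping `q` at the realistic
0.3.
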