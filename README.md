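# sfcoupling

Structure–function coupling of brain networks via regularized partial
correlation and cross-modularity.

## What it is for

Network neuroscientists routinely ask how well the functional connectivity
(FC) estimated from resting-state activity matches the anatomical
(structural) connectivity (SC) of the same brain. `sfcoupling` implements a
complete, tested pipeline for answering that question at the level of the
*whole hierarchy of nested modules* rather than single links:

- **Estimators.** From a standardized region × time panel `X` (with
  `q = N/T` not small), the sample correlation `E = XXᵀ/T` is noise-cleaned
  by six regularization methods: identity shrinkage (IS), group shrinkage
  (GS), eigenvalue clipping (PCA) and its cautious variant (cautPCA), the
  graphical lasso (GLASSO), and rotationally invariant eigenvalue cleaning
  (ORIE). FC is taken either as the regularized correlation `C` or as the
  partial correlation `J̃ᵢⱼ = Jᵢⱼ/√(JᵢᵢJⱼⱼ)`, `J = C⁻¹`, which under a
  Gaussian model keeps only direct dependencies. The regularization
  strength α is selected by validation-set likelihood over contiguous time
  folds.
- **Graphs.** `|C|`, `|J̃|` and SC matrices are sparsified at the
  *percolation threshold* — the largest cutoff at which the graph remains
  one connected component (computed exactly as the maximum-spanning-tree
  bottleneck) — or at fixed density.
- **Hierarchy comparison.** Each graph is clustered agglomeratively
  (WPGMA on the condensed distance `exp(−Aᵢⱼ)`) and, for every partition
  size `m`, the cross-modularity

  χ(m) = ( Q_F(m) · Q_S(m) · ν(m) )^(1/3)

  combines the Newman modularity of each graph under its own partition with
  the adjusted normalized mutual information ν between the two partitions.
  Its peak locates the partition at which structure and function agree best.
- **Population level.** Median population connectomes, bootstrap stability
  of the population partition, and across-module Z-scores of disease
  gene-set expression.
- **Synthetic cohorts.** A planted modular Gaussian graphical model with a
  paired structural matrix and a planted transcriptome generates ground
  truth, so every headline claim is validated as a recovery experiment.

## Worked example

```r
library(sfcoupling)

model  <- make_planted_model(n_regions = 60, n_modules = 6, seed = 1)
cohort <- make_cohort(model, n_subjects = 8, n_times = 200, seed = 2)
sweep  <- subject_sweep(cohort, methods = "GS", selection = "likelihood",
                        m_max = 20, gs_loo = TRUE)
head(sweep$records, 6)
#>   subject method role alpha   chi_max argmax_m    density
#> 1       1     GS    C  0.85 0.4548385        5 0.28644068
#> 2       1     GS   Jt  0.85 0.6831147        6 0.06440678
#> 3       2     GS    C  0.90 0.4509141        5 0.28361582
#> 4       2     GS   Jt  0.90 0.6491938        6 0.06158192
#> 5       3     GS    C  0.85 0.4372979        5 0.28587571
#> 6       3     GS   Jt  0.85 0.6710894        6 0.06666667

chi_c <- subset(sweep$records, role == "C")$chi_max
chi_j <- subset(sweep$records, role == "Jt")$chi_max
median(chi_c); median(chi_j)
#> [1] 0.4390871
#> [1] 0.6511542
compare_distributions(chi_c, chi_j, alternative = "less")$p.value
#> [1] 0.0004669931
```

Reading the output: for every subject the partial-correlation FC graph is
far sparser than the correlation one (percolation density ≈ 0.06 vs ≈ 0.29),
its cross-modularity against the subject's structural graph peaks higher
(median 0.65 vs 0.44), the peak sits at the planted coarse module count
(`argmax_m` ≈ 6), and the one-sided Mann–Whitney test confirms the contrast
(p ≈ 5·10⁻⁴). This is the package's core finding in miniature: regularized
partial correlation couples to structure better than plain correlation.

The full pipeline — cohort, sweep, population partition, bootstrap
stability, disease Z-scores, with every artifact and a manifest written to
disk — runs from one configuration:

```r
run_pipeline(list(
  cohort    = list(n_regions = 40, n_modules = 4, n_subjects = 8,
                   n_times = 120, seed = 9),
  methods   = "IS", m_max = 10,
  bootstrap = list(B = 25, m = 4, seed = 10)
), out_dir = "run1")
```

## Package layout

- `R/synthetic.R` — planted model, time-series sampler, cohort generator
- `R/estimators.R`, `R/glasso.R` — the six estimators, likelihood selection,
  partial correlation
- `R/graphs.R` — absolute-value adjacency, percolation / density cuts
- `R/hierarchy.R` — WPGMA partitions, modularity, adjusted NMI,
  cross-modularity, spectral distance
- `R/population.R` — cohort sweeps, rank tests, bootstrap stability,
  disease Z-scores
- `R/experiments.R` — the recovery-experiment drivers
- `R/io.R`, `R/pipeline.R` — delimited-text I/O, configuration, pipeline
- `vignettes/structure-function-coupling.Rmd` — the methods vignette
  (models, assumptions, parameter choices, limitations)
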