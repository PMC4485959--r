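# phylofd

Forests with more functionally diverse tree communities tend to grow
faster, but functional trait tables are expensive to assemble, and a
phylogeny is sometimes proposed as a cheap proxy for them. `phylofd` is an
analysis pipeline for asking, with forest-inventory data, how much of the
variation in stand productivity is carried by **functional diversity**,
how much by **phylogenetic diversity**, how much the two share — and how
strongly the underlying traits are structured on the phylogeny in the
first place. It is written for community ecologists working with plot
basal-area tables, a species trait table and an ultrametric chronogram.

## What it computes

**Per-plot diversity indices** (all independent of species richness;
single-species plots are assigned 0 by convention):

- *FDis*, functional dispersion: the basal-area-weighted mean distance of
  a plot's species to their weighted centroid in standardized trait
  space, `FDis = Σ aᵢ zᵢ / Σ aᵢ`.
- *PSV*, phylogenetic species variability: `PSV = (n·tr(C) − ΣC) /
  (n(n−1))` over the phylogenetic correlation submatrix of the species
  present — 1 on a star phylogeny, smaller the more related the species.
- *CWM*, the community-weighted mean of a trait, weighted by basal area.

**Phylogenetic signal per trait**:

- Pagel's λ by maximum likelihood: the Brownian-motion covariance
  `σ²V` has its off-diagonal scaled by λ ∈ [ε, 1] and the profile
  likelihood (analytic root state ẑ₀ and rate σ̂² at each λ) is maximized;
  95% confidence intervals come from a parametric bootstrap (1000
  simulations from the fitted model, refit each, percentile bounds).
- Moran's I phylogenetic correlograms: `I = (n/S₀)·ΣΣ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄) /
  Σ(xᵢ−x̄)²` with binary weights assigning each species pair to one of
  eight patristic distance classes; significance by two-sided permutation
  test (999 shuffles of tip values), null expectation `−1/(n−1)`.

**Variance partitioning** of log productivity between the FDis and PSV
blocks using adjusted R² (Ezekiel correction): unique fractions
`[a] = R²adj(both) − R²adj(PSV)` and `[c] = R²adj(both) − R²adj(FDis)`,
shared fraction `[b]`, residual `[d]`; the testable (unique) fractions
get Freedman–Lane p-values — partial F compared against 999 permutations
of the residuals of the reduced model, so 0.001 is the attainable floor.
A full multiple regression (environmental covariates + CWM of leaf N +
FDis + PSV) with per-term permutation tests is also provided.

**Synthetic data generators** (Yule chronograms, Brownian traits with
tunable λ, plot communities with log-normal basal areas, a linear
productivity response) make the whole pipeline testable end to end
without any survey data.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (each stage reads the previous stage's files under `results/`):

```sh
Rscript analysis/01_simulate.R   # chronogram + traits + plots bundle
Rscript analysis/02_indices.R    # FDis / PSV / CWM per plot
Rscript analysis/03_signal.R     # Pagel's lambda + correlograms
Rscript analysis/04_varpart.R    # variance partition + full model
```

Stage 3 prints, for traits generated with signal strengths 0.02 (maxH),
0.79 (Wd), 0.23 (Sm), 0.65 (N) and 0.82 (shade):

```
 trait lambda_hat   ci_low ci_high
  maxH   1.00e-07 1.00e-07   0.169
    Wd   7.76e-01 3.14e-01   0.915
    Sm   1.00e-07 1.00e-07   0.151
     N   5.44e-01 1.00e-07   0.779
 shade   7.17e-01 9.63e-02   0.892
```

— weak-signal traits collapse to the optimizer floor 1e-07 with CIs that
still reach well above zero on a single 61-tip tree, while strong-signal
traits are recovered near their generating values. Stage 4 prints:

```
Two-block variance partition (adjusted R-squared), n = 500
  R2adj X1 = 0.5349  X2 = 0.4108  both = 0.5662
  unique X1 [a] = 0.1554 (p = 0.001)
  shared   [b] = 0.3795 (not testable)
  unique X2 [c] = 0.0313 (p = 0.001)
  residual [d] = 0.4338
```

— most of what PSV explains is shared with FDis, and the unique
phylogenetic fraction is small, the asymmetry the generator builds in
(its FDis coefficient is 0.5 against 0.2 for PSV on correlated indices).

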