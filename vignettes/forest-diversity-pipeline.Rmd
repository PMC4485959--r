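---
title: "Linking forest productivity to functional and phylogenetic diversity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking forest productivity to functional and phylogenetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofd)
```

`phylofd` implements one coherent analysis: compute richness-independent
functional and phylogenetic diversity indices for forest plots, quantify
how much of (log) stand productivity each explains uniquely and jointly,
and characterize how strongly the traits behind the functional indices
are themselves structured on the phylogeny. This vignette explains the
statistical models, the defaults and their units, the synthetic-data
generator, and the numerical decisions, in that order.

## Diversity indices

Plots are rows of a plot × species basal-area matrix (m²/ha). Three
indices are computed per plot, all chosen to be mathematically
independent of species richness so that their effects on productivity
are not confounded with simply having more species:

* **FDis** (functional dispersion) is the basal-area-weighted mean
  Euclidean distance of the species present to their weighted centroid
  in trait space. Traits entering FDis (`maxH` maximum height in m, `Wd`
  wood density in g/cm³, `Sm` log seed mass) are z-standardized over the
  *full species pool*, not per plot, so FDis values are comparable
  across plots. Shade tolerance is an aggregate life-history score, not
  a trait per se, and is excluded from FDis; leaf nitrogen (`N`, mg/g)
  enters the analysis as a community-weighted mean instead, to capture a
  functional-identity (mass-ratio) effect rather than complementarity.
* **PSV** (phylogenetic species variability) is
  `(n·tr(C) − ΣC)/(n(n−1))` over the phylogenetic correlation submatrix
  of the species present — equivalently one minus their mean pairwise
  phylogenetic correlation. It uses presence/absence (basal area
  thresholded at zero) because it measures variability of the species
  set, not of the stand structure.
* **CWM** is the basal-area-weighted mean of a raw trait.

Single-species plots are assigned FDis = PSV = 0: a monoculture carries
no diversity of either kind, and keeping these plots in the regression
(rather than dropping them) preserves the inventory's real richness
gradient down to its floor.

On the trait distance underlying FDis: with only continuous traits, a
Gower-type dissimilarity and standardized Euclidean distance are nearly
interchangeable, and we use the latter as the simplest defensible
choice. It is a configuration argument (`fdis_traits`), not a hidden
constant.

## Phylogenetic signal

The chronogram is ultrametric with branch lengths in relative time (no
fossil calibration), so the Brownian-motion covariance of a trait is
`σ²V`, with `V[i,j]` the shared root-to-MRCA path length. Pagel's λ
rescales the off-diagonal of `V`; λ = 0 removes all phylogenetic
covariance, λ = 1 is pure Brownian motion. We estimate λ by profile
maximum likelihood: at each λ the root state and rate have closed-form
GLS solutions, leaving a 1-D bounded search over λ ∈ [ε, 1] with
ε = 1e-7.

Two numerical choices matter here:

* Because the tree is ultrametric, `V(λ) = λ(V − T·I) + T·I` shares
  eigenvectors for every λ. One symmetric eigendecomposition per tree
  therefore reduces each likelihood evaluation from O(n³) to O(n). This
  makes 1000-draw parametric bootstraps and simulation studies cheap,
  and is exactly the dense GLS likelihood (the test suite checks this
  identity against a dense-matrix oracle).
* The profile likelihood can be multimodal on small trees, so the
  optimizer evaluates a coarse grid {ε, 0.25, 0.5, 0.75, 1} and runs a
  bounded search bracketed around each grid point (tolerance 1e-8),
  keeping the best. λ is restricted to [ε, 1]: values above 1 can make
  `V(λ)` indefinite, and ε rather than exactly 0 keeps the reported
  lower CI bounds at a conventional printable floor.

Confidence intervals are parametric-bootstrap percentiles: simulate from
the fitted `(λ̂, σ̂², ẑ₀)` model, refit, take the 2.5% and 97.5%
quantiles. A replicate that fails to refit is retried once with a tiny
perturbation and then dropped with a logged count. For a trait with no
signal the bootstrap distribution piles up at ε, so the lower bound
collapses to ε — that behavior is itself a check the suite exercises. A
likelihood-ratio test of λ = 0 is attached for convenience but the CI is
the primary uncertainty summary.

λ is a single whole-tree summary, and it can miss signal that lives at a
particular depth. The complementary view is a **phylogenetic
correlogram**: Moran's I computed with binary weights restricting the
double sum to species pairs whose patristic distance falls in one of
eight classes. Classes are half-open `[lo, hi)` (last closed) so each
pair lands in exactly one class. Equal-width classes over (0, max] are
the default: when a deep split (e.g. angiosperms vs gymnosperms)
dominates the tree, intermediate classes genuinely contain no pairs and
are reported as empty rather than papered over — an equal-frequency
option exists, with quantile edges collapsing under the heavy ties that
discrete node depths induce. Weights are binary with no row
standardization, following classic phylogenetic-correlogram practice.
Significance per class is a two-sided permutation test on |I − E[I]|
(999 shuffles, p includes the observed statistic); a normal
approximation with the classical randomization moments is available as
an alternative.

## Variance partitioning

The response is log annual aboveground biomass increment
(log Mg·ha⁻¹·yr⁻¹). The two-block partition regresses it on {FDis},
{PSV} and their union, converts each R² to adjusted R² (Ezekiel
correction, `1 − (1−R²)(n−1)/(n−p−1)`), and reports unique fractions
[a], [c], the shared fraction [b] and residual [d]. Adjusted rather
than raw R² makes the fractions comparable across blocks of different
sizes; negative fractions are possible and are reported as-is.

The default partition is *unconditioned* on the environmental
covariates: the published marginal and joint values it mirrors (0.38 and
0.22 with union 0.40) are internally consistent only under the plain
two-block identities, and the covariates belong to the separate full
model (`fit_productivity_model`), which adds total basal area, organic
horizon depth, mean annual temperature and CWM of leaf N.

The unique fractions are tested by Freedman–Lane permutation: fit the
reduced model (the other block only), permute its residuals, add them
back to the reduced fitted values, refit, and compare partial F values.
Partial F is our choice of statistic — the scheme's standard, pivotal-ish
choice. The p-value counts the observed statistic
(`(1 + #{F* ≥ F})/(1 + n_perm)`), so 0.001 is the floor at the default
999 permutations. The shared fraction has no permutation test; it is not
an estimable effect of either block alone.

If the two blocks overlap or are collinear, the union design is
rank-deficient; the partition then uses the projection rank, not the
column count, as the predictor count, so duplicated blocks cleanly yield
zero unique fractions.

## The synthetic study

The generator exists so every stage can be validated end to end with
known truth. Its defaults describe one fixed synthetic study emulating a
large temperate/boreal forest inventory:

* a Yule (pure-birth) chronogram with 61 tips rescaled to unit depth —
  the analyses depend only on the chronogram's shape, not on the
  diversification model, so pure birth is the simplest adequate choice;
  a two-clade variant (basal split at 90% of depth) emulates the
  angiosperm–gymnosperm gulf that empties intermediate correlogram
  classes;
* five traits evolved under λ-transformed Brownian motion with signal
  strengths spanning the observed range for temperate tree traits —
  0.02 (maxH), 0.79 (Wd), 0.23 (Sm), 0.65 (N), 0.82 (shade) — and rates
  sized to realistic cross-species spreads (e.g. σ² = 80 m²/depth for
  maxH ≈ 9 m SD across species);
* 500 plots (configurable; the motivating inventories are 20× larger)
  whose richness is Poisson(2.5) truncated to {1..10} — monocultures
  occur, exercising the zero convention — with log-normal basal areas
  (meanlog 1.0, sdlog 0.8 in m²/ha);
* log productivity generated as `β₀ + 0.5·FDis + 0.2·PSV + 0.02·CWM_N +
  0.02·total_ba − 0.02·org_depth + 0.05·mat + N(0, 0.3²)`. FDis and PSV
  are positively correlated by construction (both increase with
  phylogenetically dispersed, trait-dispersed plots), and the larger
  FDis coefficient makes the unique-PD fraction small — the qualitative
  asymmetry the partition is designed to expose.

All generators are deterministic given a master seed, with per-stream
seeds derived by a fixed integer recurrence, and
`make_fixture_bundle()` writes byte-reproducible CSV/newick/JSON
bundles whose manifest records every true parameter.

What the generator does **not** emulate: spatial autocorrelation among
plots, climate gradients correlated with composition, allometric error
in biomass, non-Brownian (e.g. Ornstein–Uhlenbeck) trait evolution, and
measurement error in traits. Passing tests therefore demonstrate that
the estimators recover truth under their own model assumptions at
realistic sizes — not that those assumptions hold in any particular
forest inventory.

## Problem sizes used in validation

Parameter-recovery checks use 100 replicates of 200-tip trees per
generating λ (bias well under 0.1 at that size); bootstrap coverage uses
50 replicates × 200 draws; permutation-test size uses 500 null
simulations at n = 50 with 999 permutations; correlogram detection/size
checks use 50 simulations on a 61-tip two-clade tree. These sizes give
Monte-Carlo error comfortably inside the tolerance bands being checked
while keeping a full validation run in minutes.

## Known limitations

* λ estimation requires an ultrametric tree; non-ultrametric trees are
  accepted (with a warning) only for distances, VCV and correlograms.
* PSV's [0, 1] range is guaranteed only for ultrametric trees.
* The Freedman–Lane implementation assumes exchangeable residuals under
  the reduced model; strong heteroscedasticity or spatial structure
  would invalidate its size guarantee.
* Trait–tree–community label matching is exact and case-sensitive by
  design; mismatches are hard errors listing the offenders rather than
  silent drops.
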