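---
title: "Decomposing realized niches into subset-specific subniches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing realized niches into subset-specific subniches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(witomi)
library(dplyr)
```

## The model

A community survey yields three tables: environmental measurements at `n`
sampling units (sites or occasions), abundances (or occurrences) of `S`
species at the same units, and an assignment of each unit to one of `N`
subsets of the sampling domain (seasons, reaches, regions, ...).

The environmental table is standardized column-by-column under **uniform
site weights** `1/n` and the **population (divide-by-n) variance**, giving
`Z0`. The origin of this space, `G`, is the mean habitat condition of the
whole domain. Uniform weights encode the assumption that every sampling unit
is equally available to every species; the package rejects non-uniform
weighting at the interface rather than silently reweighting.

Each species `j` has a frequency profile `fr[, j]` (its column of the
abundance table divided by its total) and a marginality vector

```
m_j = sum_i fr[i, j] * Z0[i, ]
```

its mean used condition. The **outlying mean index** is `OMI_j = ||m_j||^2`,
the squared distance between the species' mean used conditions and `G`. The
ordination eigen-decomposes `C = t(M) W M` (rows of `M` are the `m_j`, `W`
the diagonal of species weights proportional to total abundance), so the
eigenvalues sum to the community's abundance-weighted average OMI and the
leading axes are the combinations of variables along which the community is,
on average, most marginal. Niche inertia decomposes per species as

```
inertia_j = OMI_j + Tol_j + Rtol_j
```

with `Tol` the tolerance (niche breadth) and `Rtol` the residual spread.

**Subniches.** Within each subset `K`, the species' profile is renormalized
over the sites of `K` (`Fr_K`), giving a subniche centroid `m_jK`. Two
marginalities are reported on the *same* OMI axes:

* `WitOMI_G = ||m_jK||^2` — measured from the overall centroid `G`; and
* `WitOMI_GK = ||m_jK - G_K||^2` — measured from the subset centroid `G_K`
  (the mean of `Z0` over the sites of `K`; equivalently the origin of the
  within-subset-centered table `Z*`).

Because all subniches refer to one ordination, they are comparable across
subsets — the point of the method. Two algebraic identities tie the pieces
together and are enforced to `1e-10` in the tests: the subniche Huygens
decomposition `inertia_K = WitOMI_G + Tol_K + Rtol_K`, and the barycenter
property `m_j = sum_K pi_jK * m_jK` with `pi_jK` the species' share of
abundance mass in `K`.

## A worked example

```{r example}
sim <- simulate_community(scenario(n_sites = c(spring = 60, autumn = 60),
                                   n_species = 6), seed = 11)
fit <- fit_omi(sim$env, sim$abund)
glance(fit)
tidy(fit) |> arrange(desc(omi)) |> head(3)

sub <- fit_subniche(fit, sim$partition)
subniche_params(sub) |> filter(present) |> head(4)
```

Permutation tests (see below):

```{r tests}
run_tests(sub, n_perm = 199, seed = 11) |> head(6)
```

Envelope geometry and the biological constraint:

```{r geometry}
envl <- build_envelopes(sub)
constraint_table(envl) |> filter(present) |> head(4)
```

`sb_percent` is the share of the existing fundamental subniche
`S_P = K ∩ N_R` (intersection of the subset's available conditions with the
species' realized niche, both as minimum convex polygons on the first two
axes) left unoccupied by the realized subniche `S_R` — the observable
footprint of biotic constraint or dispersal limitation.

## Statistical significance

Three Monte-Carlo permutation schemes, all with the `(b + 1) / (N + 1)`
p-value rule (minimum attainable p is `1 / (n_perm + 1)`, never 0) and a
default of 1000 permutations:

1. **Subset habitat conditions** — statistic `||G_K||^2`; whole rows of `Z0`
   are shuffled, preserving inter-variable correlation, under the null that
   `G_K` does not differ from `G`.
2. **Subniche marginality** — the species' within-subset frequency vector is
   shuffled across the `k` sites of the subset; `WitOMI_G` tests the null of
   ubiquity with respect to overall conditions, `WitOMI_GK` with respect to
   subset conditions. When `k! <= n_perm` the permutation group is
   enumerated exhaustively and the effective `n_perm` becomes `k!`.
3. **Species means over subsets** — the observed statistic is the mean of
   the per-subset observations and the null distribution the per-iteration
   mean of the per-subset null draws, paired by permutation index. The
   pairing convention is a design choice (the per-subset streams are
   independent); when subsets differ in effective permutation count, the
   shorter stream is recycled cyclically.

Each test draws from a substream derived from the master seed by hashing the
statistic name and the species/subset ids, so adding a species never changes
another species' p-value, and fixed seeds give bit-identical results.
P-values are reported raw; a Benjamini–Hochberg column is available as an
option (`adjust_p = TRUE`).

A calibration check (one of the shipped deep tests) simulates 500 null
communities and verifies the empirical type-I error of all three tests at
`alpha = 0.05` with 999 permutations stays within three binomial standard
errors of the nominal level.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_axes` | `min(2, p)` | factorial axes retained for displays and subniche coordinates; envelopes always use the first two |
| `tolerance` | `"direction"` | niche-breadth convention: variance along the species' own marginality direction; `"axes"` instead sums score variance over the retained axes (the two differ in how `Tol`/`Rtol` split the same spread) |
| `n_perm` | 1000 | permutations per test; at least 99 |
| `min_freq` | 0 | occupancy threshold for a site to count toward `N_R`/`S_R` membership (any presence by default) |

Degenerate inputs are defined, not errors: a species with zero marginality
has no marginality direction, so `Tol = 0` and `Rtol` carries all spread; a
species absent from a subset yields a flagged-absent record with `NA`
indexes rather than NaN propagation; a degenerate `S_P` (area 0) reports
`sb_percent = 0` with a `degenerate` flag. Eigen sign/order ambiguity is
resolved by sorting eigenvalues in decreasing order and making each
eigenvector's first non-zero loading positive, so outputs are reproducible
bit-for-bit. `S_R` is clipped to `S_P` before differencing because convex
envelopes can spill outside the intersection; without clipping `sb_percent`
could be negative.

## The synthetic generator

`scenario()` + `simulate_community()` produce communities with known niche
structure: sites drawn from correlated multivariate-normal gradients (AR(1)
correlation 0.5 by default), per-subset mean displacement of available
conditions (default: the second subset shifted +1 raw unit on the first
gradient, emulating a seasonal change in available conditions), Gaussian
(unimodal) species responses, and Poisson or negative-binomial count noise.
The default community holds 12 specialists whose optima tile the first two
gradients over ±2 units at breadth 0.6 — deliberately narrower than the unit
gradient sd, so each species' realized optimum stays close to its generating
optimum and recovery diagnostics have a clean target. Exclusion rules zero a
species in a stated raw-unit region after sampling, which installs a known
biotic-style constraint: the excluded region removes part of the realized
subniche while leaving the existing fundamental subniche in place, so
`sb_percent` has a ground truth direction.

What the generator does *not* emulate: spatial autocorrelation among sites,
zero-inflation beyond the count model, interactions among species, and
temporal dynamics. Passing recovery tests on these communities shows the
estimators track the generating structure under the stated model, not that
field data meet those assumptions.

Problem sizes used by the shipped deep checks (chosen to exercise the
estimators at realistic survey scale): 200 random instances of up to 40
sites x 5 variables x 8 species x 3 subsets for oracle equivalence and the
conservation identities; 500 replicates x 999 permutations for calibration;
recovery on 300-site communities averaged over 5 replicates (the rank
correlation is stochastic and the symmetric optimum grid contains near-tied
true displacements); 50 paired simulations for the exclusion contrast.

## Known limitations

* Environmental variables must be numeric; categorical variables need
  dummy/fuzzy coding upstream.
* Envelope geometry is restricted to the first two axes (the display
  plane); higher-dimensional hypervolume envelopes are out of scope.
* The minimum convex polygon is an envelope, not a density: it cannot show
  holes, and `S_B` from convex envelopes is an upper-bound-style summary.
* Subniche indexes are only as meaningful as the parent ordination; the
  whole-niche permutation test is provided so users can restrict
  decomposition to species with significant marginality (their parent
  p-value travels with the subniche table).
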