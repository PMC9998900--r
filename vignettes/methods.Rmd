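---
title: "Methods: multifaceted diversity along inundation gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifaceted diversity along inundation gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`multidiv` analyses plant communities arrayed along a dam-regulated
inundation gradient in three dimensions of biodiversity — taxonomic (TD),
phylogenetic (PD) and functional (FD) — at both alpha (within-community)
and beta (between-community) scales, and attributes beta diversity to
inundation, soil, climate and spatial predictors. This vignette documents
the statistical model behind each stage, the defaults and why they were
chosen, and what the synthetic-data validation does and does not
demonstrate.

## Data model

A dataset is a site-by-species community matrix (presence/absence or
abundance), a species trait table with *declared* trait kinds, a rooted
phylogeny with branch lengths, a site environment table and site
coordinates. `validate_bundle()` reconciles the species sets of
community/traits/tree and the site sets of community/env/coords by exact
label match after whitespace trimming — never fuzzy matching, because a
silent mismatch corrupts every downstream distance. With `policy = "drop"`
the common intersection is used and the tree pruned (pruning preserves
path lengths among retained tips); `policy = "error"` makes any mismatch
fatal. Sites with zero richness are dropped with a warning: every index
below is undefined on an empty community. Trait kinds live in a schema
sidecar rather than being inferred, since a column of 1/2/3 codes is
ambiguous between ordinal and categorical.

Each input row is treated as one analysis unit. Field designs often pool
quadrats into transects; the package deliberately leaves any pooling to
the user, because no single pooling rule is right for all designs.

## Alpha diversity

**Rao's quadratic entropy** $Q = \sum_i \sum_j d_{ij} p_i p_j$ over all
ordered species pairs, with $p$ the relative abundances (renormalized, so
$Q$ is invariant to abundance rescaling) and $d_{ij}$ a species distance
with zero diagonal. Taxonomic mode sets $d_{ij} = 1$ for $i \neq j$, which
reduces $Q$ to Gini–Simpson $1 - \sum_i p_i^2$; functional mode uses the
Gower distance below. In presence mode all present species get equal
weight, so taxonomic RaoQ is exactly $1 - 1/S$ — the choice is forced once
presence data are accepted, and it is the main reason RaoQ differences
between zones track richness differences in presence-mode analyses.

**Faith's PD** is the branch length of the subtree spanning the community.
The root path is included by default (`include_root = TRUE`), matching the
most common convention in community-phylogenetics software; the
alternative (subtree below the MRCA only) is available because the
convention materially changes single-species and small communities
(a 1-species site has PD = root distance under the default, 0 otherwise).

**MPD / MNTD** are the mean pairwise and mean nearest-neighbour distances
among co-occurring species, computed unweighted (presence-based) — the
beta analyses use presence/absence throughout and the unweighted forms
keep alpha and null-model machinery consistent. Both are undefined
(reported `NA`, never an error) below 2 species.

## Null models and SES

Community structure is assessed with
$\mathrm{SES} = (\mathrm{obs} - \overline{\mathrm{null}})/\mathrm{sd}_{\mathrm{null}}$
against a **taxa-label shuffle**: one random permutation of species
identities applied jointly to rows and columns of the species distance
matrix, with the occurrence matrix held fixed. This preserves observed
richness at every site exactly, conserves the multiset of distances, and
is the least-assumption null consistent with a richness-preserving
design; it is equivalent to shuffling tip labels on the tree. Occurrence
matrix randomizations (independent/trial swap) answer a different question
and are deliberately out of scope. Defaults: 1000 replicates, seed
mandatory, `p_rank` uses the $(r+1)/(n+1)$ convention so p-values are
never zero. Degenerate nulls (a site holding the entire pool, where
shuffling changes nothing) are flagged, never silently dropped.

One permutation per replicate is shared across all sites
(`shared_null = TRUE`), so within a replicate the site values are
comparable; per-site independent permutations are available and agree in
distribution. SES < 0 indicates clustering, SES > 0 overdispersion, and
|SES| > 1.96 significant deviation at the two-sided 5% level.

## Trait space

**Gower distance** handles the five mixed-type riparian traits (dispersal
type, growth form, life cycle: categorical; flowering phenology: ordinal
months; shoot height: continuous metres). Per-trait dissimilarity is a
0/1 mismatch (categorical), range-normalized absolute difference
(continuous, pool-wide range recomputed after any species drop so results
are stable per bundle), or range-normalized difference of average ranks
(ordinal — the conventional rank scaling, chosen because no published
convention for phenology months is universal). Missing values use
pairwise deletion with weight renormalization; a pair sharing no trait is
an error rather than NaN. Weights default to equal — no weighting scheme
is obviously better, and equal weights are the transparent baseline.

**Functional dendrogram**: UPGMA of the Gower matrix, with deterministic
lexicographic tie-breaking so functional beta diversity is reproducible
bit-for-bit across platforms. **PCoA** (double-centered $-\tfrac12 D^2$
eigendecomposition) supplies continuous trait-space coordinates and the
multivariate response for variance partitioning; with no correction, axes
with eigenvalues below tolerance are dropped and the negative-eigenvalue
count reported; Lingoes/Cailliez corrections are available.

## Beta diversity partitioning

The Sørensen family decomposes total dissimilarity into **turnover**
(species replacement) and **nestedness-resultant** (richness-difference)
components: for shared/unique quantities $(a, b, c)$,

$$\beta_{sor} = \frac{b+c}{2a+b+c}, \qquad
  \beta_{sim} = \frac{\min(b,c)}{a+\min(b,c)}, \qquad
  \beta_{sne} = \beta_{sor} - \beta_{sim},$$

with the additivity identity holding to 1e-12 everywhere. The three
dimensions differ only in the currency of $(a, b, c)$: species counts;
branch lengths shared between the two communities' root-inclusive
spanning subtrees (so $a + b$ is exactly Faith's PD of the first site);
or functional units. On a star tree with unit branches the phylogenetic
partition collapses to the taxonomic one exactly — a structural identity
used in the tests.

Functional beta defaults to **dendrogram mode** (shared branch length on
the UPGMA dendrogram): it is deterministic, accommodates categorical
traits, and needs no axis-count choice. **Hull mode** (shared convex-hull
area of the two communities in the first 2 PCoA axes) is provided because
it is the convention of widely used functional-beta software, but it
requires continuous coordinates and at least 3 species per site, and the
two modes are not numerically interchangeable — the mode used is stamped
into outputs. Hull mode is implemented for 2 axes (convex polygon
clipping); higher-dimensional hull intersection is not supported and
raises an error pointing to dendrogram mode.

Multiple-site values use Baselga's formulas over
$\sum_{i<j} \min(b_{ij}, b_{ji})$, $\sum_{i<j} \max(b_{ij}, b_{ji})$ and
the pooled shared component $\sum_i S_i - S_T$, applied to the same
currencies. Because published "overall beta" figures do not always state
whether they are multiple-site values or means of pairwise values, both
are reported side by side.

## Spatial and environmental predictors

**PCNM**: geographic distances above a truncation threshold $t$ (default:
the largest minimum-spanning-tree edge, the standard choice that keeps the
site graph connected) are replaced by $4t$; the matrix is double-centered
and eigendecomposed. Positive-eigenvalue axes (positively autocorrelated
spatial patterns) are exposed by default; negative-eigenvalue axes sit
behind a flag. Retained axes are orthogonal and centered (checked to
1e-8).

**Environment**: all predictors are centered and scaled — the population
SD convention (divide by $n$) is used and recorded; constant columns are
dropped with a warning. Soil and climate families are each reduced by
correlation-matrix PCA, retaining axes that explain more than 10% of the
variance (threshold configurable); axis signs are fixed so the
largest-magnitude loading is positive, making scores deterministic. The
inundation gradient enters models as the zone's inundation days
(68/112/152/204), standardized — a quantitative coding that preserves the
ordering and spacing of the flooding regime; a categorical-zone option
exists because the correct coding is a modelling judgement.

## Inference

**Mantel tests** correlate the $n(n-1)/2$ off-diagonal elements of two
aligned distance matrices; the null permutes rows/columns of one matrix
jointly, and the one-tailed p uses $(r+1)/(n+1)$. The **partial Mantel**
test correlates the residuals of both matrices after regression on a
third, permuting one raw matrix and re-residualizing (residual-correlation
method with raw-matrix permutation) — conventions differ between
implementations, so this one is documented and seed-deterministic. On
fixed matrices the statistic equals the first-order partial correlation
formula. Degenerate (constant) matrices — e.g. the nestedness component
of a fixed-richness design, which is identically zero — yield `NA` with a
warning rather than an arbitrary number. The 18 Mantel cells of the
standard output (3 dimensions × 3 components × 2 predictors) are left
uncorrected for multiplicity by default, mirroring common reporting; Holm
correction can be applied downstream.

**Variance partitioning** uses the positive-eigenvalue PCoA axes of a
beta-dissimilarity matrix as a multivariate response (db-RDA style; the
construction is recorded in the output), fits multivariate least squares
for all 15 non-empty unions of the four predictor sets, converts each fit
to Ezekiel-adjusted $R^2 = 1 - (1-R^2)\frac{n-1}{n-m-1}$ (with $m$ the
raw predictor-column count, so redundant columns cost degrees of freedom),
and solves the inclusion–exclusion system exactly, so the 15 Venn
fractions always reconstruct every union's adjusted R² to 1e-10 and sum
to the global adjusted R². Slightly negative fractions are an inherent
adjusted-R² artifact and are reported as-is; clamping would destroy the
sum identity. In `run_pipeline()` the spatial axes are truncated
(broadest scales first) only if the predictor total would otherwise
saturate the model ($n - m - 1 \le 0$).

**Forward selection** adds the candidate with the largest adjusted-R²
gain, requiring a permutation p ≤ α for the added term (Freedman–Lane
residual permutation under the current model) and stopping once the
selected model's cumulative adjusted R² reaches the global
(all-candidate) adjusted R². The global-R² criterion is applied *after*
an accepted addition rather than as a veto of the addition that crosses
it: with noise among the candidates, the global adjusted R² is depressed
by their degrees-of-freedom cost, and a strictly applied veto would
reject a single strong causal predictor about half the time even though
selecting it is unambiguously correct. Applied this way the criterion
retains its purpose — no chasing of redundant variance once the signal is
captured — without that pathology.

## The synthetic-data generator

The generator produces datasets whose assembly mechanism is known, so the
analysis chain can be validated end-to-end:

- **Phylogeny**: Yule (pure-birth) tree, unit birth rate.
- **Traits**: shoot height from exponentiated Brownian motion; flowering
  phenology as a discretized Brownian trait (ordinal months 4–9);
  dispersal type, growth form and life cycle from symmetric k-state
  Markov processes (rate 0.3 per unit branch length — labile enough to
  vary, conserved enough to carry phylogenetic signal). Each species also
  carries a latent **elevation optimum**, Brownian on the tree and mapped
  to the 145–175 m band through a square-root transform: most of the
  regional flora is flood-intolerant with optima in the rarely inundated
  upper band, and only a phylogenetically restricted tail tolerates the
  low elevations — the causal chain by which environmental filtering
  produces phylogenetic clustering. A flag decouples optima from the
  phylogeny to test the contrary case.
- **Landscape**: sites sit at cross-sectional locations along a 600 km
  1-D channel (a river network is effectively one-dimensional for
  dispersal), each location carrying one site per elevation zone
  (I: 170–175 m / 68 days of inundation; II: 165–170 / 112;
  III: 160–165 / 152; IV: 145–160 / 204), so zone is orthogonal to
  along-channel position as in a cross-sectional transect design. Eleven
  soil variables trend log-linearly with elevation (nutrients and
  moisture enrich downslope) plus correlated noise; climate (MAT around
  18.22 °C, MAP around 1110 mm) follows a smooth along-channel gradient
  plus noise.
- **Assembly**: per site, occurrence weight =
  $\exp(-(\mathrm{opt}_s - \mathrm{elev})^2 / 2\sigma^2)$ (filtering,
  niche breadth σ in metres) ×
  $\exp(-|x_{site} - \mathrm{center}_s| / \lambda)$ (dispersal,
  decay scale λ in km); a fixed per-site richness is drawn without
  replacement with these weights, so the generative design matches the
  richness-preserving null models exactly. `neutral` switches both terms
  off; `nested_loss` builds strict subset chains (prefixes of one species
  ranking, richness decreasing along the gradient); `turnover` assigns
  disjoint zone pools.

The `paperlike` preset freezes the emulated study conditions: a
166-species pool, 64 sites (16 locations × 4 zones), per-zone richness
targets 26/21/16/11 (diversity declines with inundation) and per-zone
niche breadths σ = 12/8/5/3 m (flooding stress filters more strongly
downslope), λ = 150 km, both assembly terms active.

**What passing tests show — and don't.** The generator validates that the
pipeline *recovers* filtering (negative SES, monotone in σ), dispersal
limitation (positive space–beta Mantel, dominant pure-spatial fraction),
nestedness vs turnover structure, and neutral calibration (mean SES ≈ 0,
|SES| > 1.96 rate ≈ 5%, Mantel type-I ≈ 5%). It does not model species
interactions (no competition, so overdispersion at benign sites is out of
recovery scope), temporal dynamics, explicit hydrology, abundance
structure, or sampling error — so passing tests demonstrate correctness
of the statistical machinery under the stated mechanisms, not that real
riparian data meet those mechanisms.

## Numerical choices and problem sizes

Distance matrices are symmetrized and validated on entry (symmetry to
1e-8); eigenvalue cutoffs are relative (1e-8 of the largest magnitude);
UPGMA ties break lexicographically; all permutation-based results are
pure functions of their seed; pipeline outputs contain no timestamps, so
re-runs are byte-identical. The validation suite uses pools of 20–166
species and 8–64 sites, 199–1000 null replicates, 99–999 permutations,
and 500-community / 500-run calibration batches; the full `paperlike`
pipeline (166 species, 64 sites, 1000 nulls, 999 permutations) is the
largest routine configuration and the scale at which determinism is
verified.

## Known limitations

- Hull-mode functional beta is 2-D only; no multi-site hull variant.
- No abundance-weighted (Bray–Curtis) or Jaccard-family decomposition;
  the Sørensen presence/absence family only.
- No Hill-number generalization of the alpha indices.
- No occurrence-matrix null models (the occurrence matrix is fixed by
  design).
- No linear mixed models or spatial autocorrelation structures for alpha
  diversity; standard modelling packages handle that downstream.
- Geographic ingestion expects pre-extracted per-site climate values; no
  raster/shapefile support.
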