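# multidiv

Multifaceted diversity analysis of riparian plant communities along
dam-regulated inundation gradients: taxonomic (TD), phylogenetic (PD) and
functional (FD) alpha and beta diversity, null-model community structure,
and attribution of beta diversity to inundation, soil, climate and spatial
factors.

Reservoirs flood their shores on a schedule set by dam operation; the
resulting inundation gradient (here four elevation zones experiencing 68,
112, 152 and 204 days of flooding per year) filters the species, traits and
lineages that can persist at each elevation, while distance along the
channel limits which species ever arrive. `multidiv` implements the full
statistical toolchain used to disentangle these processes, plus a synthetic
community generator with *known* assembly mechanisms so that every stage can
be validated against ground truth.

## What it computes

**Alpha diversity** (per community):

- Rao's quadratic entropy `Q = Σᵢ Σⱼ dᵢⱼ pᵢ pⱼ` with relative abundances
  `p` and distances `d`: taxonomic mode (`dᵢⱼ = 1`, i.e. Gini–Simpson) and
  functional mode (Gower distance over mixed traits);
- Faith's phylogenetic diversity (spanning branch length, root-inclusive by
  default);
- MPD and MNTD (mean pairwise / nearest-taxon distance) on cophenetic or
  trait distances.

**Null models**: standardized effect sizes
`SES = (obs − mean_null) / sd_null` under a richness-preserving taxa-label
shuffle (1000 replicates by default); `SES < 0` indicates clustering,
`SES > 0` overdispersion, `|SES| > 1.96` significant deviation.

**Beta diversity**: Baselga's Sørensen-family decomposition into turnover
(`β_sim`) and nestedness (`β_sne`) components, pairwise and multiple-site,
in three dimensions — species counts (taxonomic), shared branch lengths on
the phylogeny (phylogenetic), and shared branch lengths on a UPGMA
functional dendrogram or shared convex-hull area in trait space
(functional).

**Drivers**: PCNM spatial eigenvectors from truncated geographic distances,
PCA reduction of soil/climate variable families (axes explaining > 10%
retained), Mantel and partial Mantel permutation tests, and four-set
variance partitioning (inundation, climate, soil, space) of db-RDA style
adjusted R² with exact inclusion–exclusion Venn fractions and forward
selection.

**Synthetic data**: Yule trees, Brownian/Markov trait evolution with
phylogenetically conserved elevation optima, a riverbank landscape with four
elevation zones and elevation-trending soils, and community assembly under
`neutral`, `filtering`, `dispersal`, `nested_loss`, `turnover` and `mixed`
scenarios.

## Worked example

```r
library(multidiv)

# 80-species pool, 32 sites, environmental filtering with niche breadth 4 m
b <- simulate_dataset(scenario("filtering", S = 80, N = 32, richness = 12,
                               sigma = 4, seed = 11))

alpha <- alpha_pipeline(b)
head(alpha[, c("site", "richness", "raoq_td", "raoq_fd", "faith_pd",
               "mpd_phylo", "mntd_phylo")], 3)
#>      site richness raoq_td raoq_fd faith_pd mpd_phylo mntd_phylo
#> 1 site001       12  0.9167  0.4420    20.12     4.287      2.274
#> 2 site002       12  0.9167  0.4627    25.06     5.394      3.117
#> 3 site003       12  0.9167  0.4905    23.00     5.799      2.579

ses <- ses_diversity(b, "mntd", "phylo", n_null = 999, seed = 1)
mean(ses$ses, na.rm = TRUE)
#> [1] -0.932
sum(ses$ses < -1.96, na.rm = TRUE)
#> [1] 5

beta_multisite(b$community, "taxonomic")
#> taxonomic multi-site beta: SOR 0.9426 = SIM 0.9426 + SNE 0.0000
#>   turnover 100.00%, nestedness 0.00% (n = 32 sites); mean pairwise sor 0.8422
```

The mean SES(MNTD) of −0.93 recovers the phylogenetic clustering that the
filtering scenario builds in (co-occurring species share phylogenetically
conserved elevation optima), and — because every site has the same richness
by design — taxonomic beta diversity is pure turnover (`SNE = 0`).

`run_pipeline()` executes the whole analysis (alpha → SES → beta → PCNM/PCA
→ Mantel → variance partitioning) from one config and writes one CSV per
stage plus a `manifest.yaml` recording every option and seed:

```r
run_pipeline(list(scenario = "paperlike", seed = 1, out_dir = "out"))
```

A thin command-line wrapper is installed at
`inst/scripts/multidiv.R` (`Rscript multidiv.R --config run.yaml`).

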