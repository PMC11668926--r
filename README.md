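# riversed

Analysis toolkit for spatially structured sediment (and other benthic)
bacterial communities profiled by 16S amplicon sequencing. The package
targets the standard question set for abundant vs. rare taxa along a
large river: how are taxa partitioned between the abundant fraction and
the rare biosphere, how do alpha and beta diversity vary over seasons
and landforms, how fast does community similarity decay with along-river
distance, which taxa form non-random co-occurrence networks and which
are keystones, which ecological processes (selection vs. dispersal vs.
drift) assemble each subcommunity, and which environmental factors
explain the turnover. It is written for microbial ecologists who have an
ASV count table, a rooted phylogeny and sample metadata — or who want a
fully synthetic, ground-truthed stand-in for method validation.

## What it computes

* **Abundance classes.** With per-sample relative abundances of ASV *i*
  summarised by (min, max) across samples and thresholds 0.01 % (rare)
  and 1 % (abundant): AAT (always abundant), CAT (conditionally
  abundant), CRAT (conditionally rare and abundant), MT (moderate), CRT
  (conditionally rare), ART (always rare). CRAT form the abundant
  fraction; CRT + ART form the rare biosphere.
* **Diversity.** Chao1 (bias-corrected, `S_obs + F1(F1−1)/(2(F2+1))`),
  Shannon–Wiener (nats), Faith PD (root-inclusive), Good's coverage
  `1 − F1/N`; Bray–Curtis and unweighted UniFrac distance matrices.
* **Spatial patterns.** Distance-decay: OLS of pairwise similarity
  `1 − d_ij` on along-river separation `|x_i − x_j|`, permutation p;
  global and pairwise ANOSIM (rank-based R with add-one permutation p).
* **Co-occurrence networks.** Spearman ρ > 0.8, p < 0.01 edges over
  prevalence-filtered (≥ 20 % detection) ASVs; node degree, raw
  betweenness, per-component closeness; Erdős–Rényi G(n, m) null
  ensembles; power-law vs. Gaussian degree-distribution fits (adjusted
  R²); keystone nodes (degree > 100, betweenness < 5,000); observed vs.
  random co-existence (O/R) ratios between taxon groups.
* **Assembly processes.** βMNTD and βNTI (z-score against tip-shuffling
  nulls, compiled in C++), Raup–Crick on Bray–Curtis (RCbray, rescaled
  to [−1, 1]), and the five-way rule: βNTI > 2 heterogeneous selection,
  βNTI < −2 homogeneous selection, otherwise RC > 0.95 dispersal
  limitation, RC < −0.95 homogenizing dispersal, else undominated.
* **Environmental attribution.** Mantel and partial Mantel tests
  (Spearman, geographic control), single-factor environmental distances
  on z-scores, and two-set variance partitioning via RDA on
  Hellinger-transformed counts with Ezekiel-adjusted R².
* **Synthetic data.** A generator with lognormal regional abundances,
  Brownian-motion niche conservatism on a Yule phylogeny, an
  along-river environmental gradient, seasonal offsets, dispersal
  kernels, demographic drift, finite local communities and planted
  co-occurrence modules — with regime presets whose expected assembly
  process is known, so every stage can be validated against truth.

## Worked example

```r
library(riversed)
cfg <- sim_config(n_sites = 12, n_seasons = 2, n_taxa = 120,
                  depth = 5000, regime = "heterogeneous_selection",
                  seed = 42)
ds   <- simulate_dataset(cfg)
rare <- rarefy(ds$counts, seed = 1)

classify_asvs(rare)
#> Abundance-class partition of 119 ASVs (rare < 0.0001, abundant >= 0.01)
#>  AAT  CAT CRAT   MT  CRT  ART
#>    0    0   58    0   61    0
#> 1 ASV(s) absent everywhere were dropped

b  <- beta_nti(rare, ds$tree, n_null = 199, seed = 1, weighted = FALSE)
rc <- raup_crick_bray(rare, n_null = 199, seed = 2)
round(process_fractions(classify_processes(b, rc))[
  , c("heterogeneous_selection", "undominated", "deterministic")], 3)
#>   heterogeneous_selection undominated deterministic
#> 1                   0.743       0.203         0.746

anosim(bray_curtis(rare),
       setNames(ds$metadata$season, ds$metadata$sample_id),
       n_perm = 999, seed = 3)
#> ANOSIM R = -0.0770 (p = 0.995, 999 permutations)

distance_decay(bray_curtis(rare),
               setNames(ds$metadata$dist_to_mouth_km,
                        ds$metadata$sample_id),
               n_perm = 999, seed = 4)
#> Distance-decay: slope -0.167 /1000km (R^2 = 0.486, p = 0.001, 276 pairs)
```

Reading the output: the generator planted strong phylogenetically
conserved selection along the river gradient with no seasonal effect on
community structure beyond a small niche shift. The pipeline recovers
exactly that: ~74 % of sample pairs classify as heterogeneous selection,
seasons do not separate (ANOSIM R ≈ 0, p ≈ 1), and similarity decays
significantly along the river (negative slope, permutation p = 0.001).

The full workflow (rarefaction → partition → diversity → spatial →
network → assembly → environmental attribution) runs from one
configuration via `run_pipeline()`; see
`inst/cli/riversed-pipeline.R` for the command-line entry point and
`vignettes/riversed-methods.Rmd` for the methodological choices.

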