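---
title: "riversed: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riversed: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind each stage of the
package, the conventions that had to be pinned for reproducibility, and
the design choices made where the methodology is genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The analysis model

The package implements the standard comparative workflow for abundant
versus rare bacterial taxa in spatially structured communities: an ASV
count table is rarefied to even depth, every ASV is assigned to one of
six abundance classes, and the resulting subcommunities (the abundant
CRAT fraction and the rare CRT/ART fractions) are compared in terms of
diversity, spatial turnover, co-occurrence structure, assembly
processes and environmental correlates.

### Abundance classes

Classification uses the per-sample relative abundance of each ASV,
summarised by its minimum and maximum across samples, with two
thresholds: rare below 0.01 % and abundant at or above 1 %. The six
classes (AAT, CAT, CRAT, MT, CRT, ART) are exhaustive and mutually
exclusive over ASVs with a positive total. Boundary convention: the
quoted inequalities are taken literally, so "≥" applies at both cuts —
an ASV sitting exactly at 0.01 % everywhere is moderate (MT), not rare.
Classification is computed on the rarefied table (matching the order of
operations rarefy → classify), pooled across seasons by default; ASVs
absent from a sample have relative abundance zero there, which counts
toward "min < 0.01 %".

### Diversity

* **Chao1** uses the bias-corrected denominator `2(F2 + 1)` so the
  estimate is defined when no doubletons are observed.
* **Shannon–Wiener** is reported in natural log — the default of the
  ecology toolkits this workflow descends from. This is a declared
  convention, not something the upstream methodology states.
* **Faith PD** is root-inclusive: the score of a single-tip sample is
  its root-to-tip path length. This convention must be pinned for
  reproducibility; it is the dominant one.
* **Unweighted UniFrac** follows the branch-indicator formula
  `Σ l_b |I_A(b) − I_B(b)| / Σ l_b max(I_A(b), I_B(b))`, where
  `I_X(b)` marks branches with at least one descendant tip present in
  X. A consequence worth spelling out: for two single-tip samples on
  the two leaves of a cherry, the stem above the cherry is shared (it
  has descendants in both), so the distance is 2/3 on the tree
  `((A:1,B:1):1,C:2);`, not 1. UniFrac is computed on presence/absence
  after rarefaction.

### Spatial patterns

The river is one-dimensional, so the geographic separation of two
samples is the absolute difference of their distances to the river
mouth; distance-decay regresses pairwise Bray–Curtis *similarity*
(`1 − d`) on that separation by ordinary least squares, reporting the
slope per 1,000 km. Significance comes from permuting sample
identities in the geographic vector, two-sided on |slope|. ANOSIM is
the classic rank statistic `R = (mean between − mean within)/(n(n−1)/4)`
over the ranked dissimilarities. All permutation p-values use the
add-one rule (the observed labelling counts as one permutation), so
p = 0 is impossible and the tests are valid (super-uniform under the
null — this is verified by a 500-replicate calibration test).

### Co-occurrence networks

Edges require Spearman ρ > 0.8 **and** p < 0.01 on the
prevalence-filtered table (ASVs detected in ≥ 20 % of samples).
Choices pinned here:

* the threshold is one-sided (positive co-occurrence), matching the
  stated rule `r > 0.8`; an `absolute = TRUE` flag admits |ρ| > 0.8;
* p-values come from the t approximation on n − 2 df with average-rank
  ties, and are used raw (no multiple-testing correction) by default,
  with an optional Benjamini–Hochberg flag — fidelity first, rigor
  available;
* the null ensemble is G(n, m) — uniform simple graphs with exactly
  the observed node and edge counts — because the comparison demands
  "equivalent numbers of nodes and edges", not an edge probability;
* betweenness is raw (unnormalised) shortest-path counts, because the
  keystone cutoff (betweenness < 5,000 with degree > 100) is on a raw
  scale; closeness is normalised within connected components;
* degree-distribution fits: the power law is OLS on log10 frequency vs
  log10 degree over positive-frequency degrees; the Gaussian
  `a·exp(−(k−μ)²/(2σ²))` is least-squares on the integer-degree
  spectrum over the full observed range (zero-frequency integers
  included, no rebinning); adjusted R² applies the usual
  `1 − (1−R²)(n−1)/(n−p−1)`.

A point uncovered while validating the Erdős–Rényi contrast: the
Gaussian fit to a *single* G(1212, 20655) graph has adjusted R² around
0.97, bounded by Poisson-level noise in the per-degree counts (the
residual sum approaches the node count while the spectrum's total sum
of squares is fixed). The published fit quality of 0.98+ describes the
degree spectrum of the pooled 10,000-graph ensemble, which is what the
acceptance protocol therefore fits (pooling scaled down to 100 graphs
per seed; the pooled spectrum has the same shape with ~100× less bin
noise).

### Assembly processes

βMNTD between samples A and B is
`½ [Σ_i f_iA · min_{j∈B} d(i,j) + Σ_j f_jB · min_{i∈A} d(j,i)]` with
patristic distances d and within-sample relative abundances f
(`1/richness` in the unweighted variant). βNTI standardises the
observed βMNTD against nulls that shuffle taxon labels across all tips
of the supplied tree (the regional-pool shuffle; 999 replicates by
default), the canonical choice of the null-model framework. For
subcommunity analyses the tree is pruned to the subcommunity's taxa.
Pairs whose null distribution is degenerate (sd = 0, e.g. on a star
tree) are reported missing rather than forced. The null loop is
compiled (Rcpp) because it dominates runtime.

RCbray preserves each sample's observed richness and read total,
draws which taxa occur with probability proportional to regional
occupancy (without replacement), allocates remaining reads
proportionally to regional relative abundance, and ranks the observed
Bray–Curtis within the null distribution, rescaled to [−1, 1]. Two
implementation decisions:

* null communities are drawn once per sample and reused across pairs.
  A pair's null distribution is identical to the per-pair protocol
  (sample A's null never depends on B); only independence *between*
  pairs is sacrificed, and RC values are consumed marginally — this
  turns an O(pairs) null cost into O(samples);
* ties between a null draw and the observed value count half, with a
  relative tolerance of 1e-10, so floating-point coincidences do not
  flip RC between seeds.

The five-way rule is strict at its boundaries exactly as quoted:
βNTI = ±2 and RC = ±0.95 fall to the non-selection / non-dominant
side.

### Environmental attribution

Mantel statistics default to Spearman correlation of the unfolded
lower triangles; partial Mantel uses the first-order partial formula
and permutes the second matrix. Single-factor environmental distances
are absolute differences of z-scores, making them invariant to affine
changes of measurement scale. Variance partitioning
Hellinger-transforms the community matrix (counts in a linear
ordination), computes RDA R² as the share of total variance captured
by the fitted multivariate regression, adjusts with Ezekiel's formula,
and reports `a = adj(∪) − adj(set2)`, `b = adj(1) + adj(2) − adj(∪)`,
`c = adj(∪) − adj(set1)`, `d = 1 − adj(∪)`. Raw fractions sum to 1
exactly; reported fractions truncate negatives at 0 with the raw
values preserved. The Wilcoxon rank-sum test enumerates all group
assignments exactly for n ≤ 12 (average-rank ties) and otherwise uses
the tie-corrected normal approximation without continuity correction;
Kruskal–Wallis applies the standard tie correction with a chi-square
reference.

## The synthetic world

The generator emulates the sampling design this workflow is built for:
~24 sites along a 4,300 km river, two seasons, lognormal regional
abundances (sdlog 2 puts most taxa in the rare biosphere), a Yule
phylogeny with Brownian-motion niche optima (phylogenetically
conserved niches — the signal βNTI assumes; a "shuffled" mode destroys
it), nine measured environmental factors generated as linear
along-river trends plus seasonal offsets and noise (TOC gets an extra
independent component so a TOC-specific association can be planted),
landform classes as position quintiles, exponential dispersal kernels
around per-taxon home sites, and optional planted co-occurrence
modules (a shared per-sample lognormal factor multiplying member
weights; members are taken from the top regional abundances so the
signal survives the prevalence filter).

Sampling weight of taxon i in sample s:

`w_i(s) = A_i · exp(−α (μ_i − E_s)² / (2σ²)) · K_i(s) · drift`,

counts are multinomial at the configured depth, optionally through a
finite local community (a first multinomial draw of N individuals,
then sequencing reads from that composition — Hubbell-style drift that
no sequencing depth can average away).

### Regime presets and what "recovery" means

Four presets correspond to the four decisive classes of the
(βNTI, RCbray) framework, and the regime-recovery tests demand the
matching class be modal:

* **heterogeneous selection** — strong conserved selection (α = 20)
  along the site-varying gradient;
* **homogeneous selection** — the same filter applied identically at
  every site. Three ingredients were needed to make this regime
  *detectable*, all fixed in a design pre-study and frozen: the shared
  optimum sits 1.5 sd off the trait-distribution centre (a
  centre-valued optimum selects taxa from many clades, because
  Brownian traits regress to the mean, and carries almost no
  phylogenetic signal); demographic drift (sdlog 2) plus a finite
  local community (150 individuals) create taxonomic turnover between
  samples — taxa shared by a pair contribute zero to βMNTD under
  *every* tip shuffle, so near-identical communities are
  uninformative; and the harsh filter flattens regional abundances
  (sdlog 1). Recovery analyses use presence-based (unweighted) βMNTD
  because the planted signal lives in presence structure; the package
  default remains abundance-weighted;
* **dispersal limitation** — no selection, home sites with an
  exponential kernel (λ = 0.01/km against ~190 km site spacing);
* **neutral / well-mixed** — every sample is a multinomial draw from
  one shared pool. Its expected class is **homogenizing dispersal**,
  not "undominated": unconstrained dispersal from a shared pool makes
  communities *more similar* than the richness/abundance-constrained
  Raup–Crick null, which is precisely what RC < −0.95 flags, and is
  the ecological meaning of mass effects. "Undominated" is the
  signature of intermediate dispersal plus drift — a scenario the
  presets deliberately exclude.

### What a green test does and does not establish

The generator plants clean, single-mechanism worlds with far fewer
taxa (hundreds, not tens of thousands), no sequencing error, no
compositional bias, perfectly known trees and noise-free metadata.
Green recovery tests establish that the statistics respond to the
structures they are supposed to detect, at realistic effect sizes, and
that the implementations match independent oracles; they do not
establish sensitivity at real-data scale, robustness to tree error, or
anything about taxonomic assignment.

## Numerical choices and degenerate inputs

* All permutation tests: add-one p, observed labelling included;
  exhaustive enumeration available for tiny n (used by the tests).
* Rarefaction: sampling without replacement per sample; rows below the
  target depth are dropped with a warning (or rejected by flag);
  full-depth rows pass through unchanged; a fixed seed gives
  bit-identical output, and the caller's RNG state is never disturbed.
* Seed discipline: a single master seed, with per-stage seeds derived
  by a fixed affine map kept inside 32-bit range, so independent stage
  re-runs reproduce the pipeline exactly.
* Degenerate cases: empty samples give missing coverage/Shannon;
  both-empty pairs give missing Bray–Curtis; zero-variance ASVs are
  excluded from correlation networks with a warning; constant factors
  give all-zero environmental distances with a warning; collinear
  predictor sets are rejected naming the offending columns; βNTI with
  sd(null) = 0 is missing, and such pairs are excluded (and counted)
  in process fractions.
* Configuration files are JSON rather than YAML so the pipeline runs
  on a guaranteed-present parser.

## Known limitations

* The rarefaction depth of the motivating study design is unstated;
  the default (minimum sample total) is the stated rule, not a known
  value. Whether coverage was computed pre- or post-rarefaction is
  likewise unstated; the package computes it on whatever table it is
  given.
* Spearman p-values use the t approximation, not the exact
  permutation distribution; at small n with the ρ > 0.8 / p < 0.01
  double threshold the ρ criterion dominates in practice.
* Distance-decay slopes depend on the (unstated) distance unit of any
  published comparison; slopes here are per 1,000 km by declaration.
* The RCbray null is the classic occupancy/abundance-constrained
  draw; it is not a perfect model of multinomial sampling noise, which
  is exactly why a well-mixed world registers as homogenizing
  dispersal (see above) — an interpretation to keep in mind with very
  deeply sequenced, low-richness data.
* No SparCC/SPIEC-EASI-style compositional correction is applied in
  networks (plain Spearman is the implemented protocol); modularity
  detection, NMDS, forward selection and db-RDA are out of scope.
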