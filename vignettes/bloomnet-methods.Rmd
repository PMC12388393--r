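---
title: "Models and methods behind bloomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bloomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bloomnet)
```

`bloomnet` implements a comparative analysis of paired 16S/18S amplicon
communities between a dinoflagellate bloom region (BR) and a reference
region (NR). This vignette explains the statistical machinery, the design
of the synthetic community generator the tests rest on, and the numerical
choices made where the methods literature leaves latitude.

## The analysis chain

The pipeline follows the standard order for bloom-impact surveys:
taxonomic cleanup → minimum-depth rarefaction → alpha/beta diversity →
environment-constrained ordination → per-region co-occurrence networks.

**Cleanup.** Prokaryote tables drop ASVs with `Chloroplast` or
`Mitochondria` at any lineage rank; eukaryote tables drop `Metazoa` and the
macro-/land-plant lineages (`Rhodophyta`, `Streptophyta`,
`Trebouxiophyceae`, `Ulvophyceae`); both drop phylum-level unclassified
ASVs. Matching is case-insensitive on *whole rank names*: a lineage
containing `Chloroplastida` (a green-algal clade) must not be caught by the
`Chloroplast` rule, so substring matching is deliberately avoided.

**Rarefaction.** Each sample is subsampled without replacement to the
minimum library size (vegan's `rrarefy`), so per-ASV counts follow a
multivariate hypergeometric distribution; a seed is mandatory because the
subsample is random. Presence for the shared-ASV (Venn) summary is
evaluated *before* rarefaction — one read after cleanup counts as presence
— because shared/total ASV counts in survey reports precede
normalization-dependent losses. This is a documented assumption, not a
mathematical necessity.

**Alpha diversity.** Shannon entropy uses the natural logarithm so that
Pielou's evenness J = H / ln S is internally consistent; J is undefined
(reported `NA`) for single-ASV samples. Wilcoxon rank-sum tests use the
exact null when the pooled n is at most 20 and tie-free, otherwise the
normal approximation with tie and continuity corrections.

**Beta diversity.** Bray–Curtis dissimilarities feed classical PCoA (Gower
double-centering, eigendecomposition). Axis percentages divide by the sum
of *positive* eigenvalues only; negative eigenvalues — routine for
Bray–Curtis — are reported raw by default, with the Cailliez correction
behind a flag. Reporting raw values is the transparent default; corrected
and uncorrected axis percentages are not comparable, so the choice is never
silent. PERMANOVA partitions the squared dissimilarities (Anderson's
pseudo-F) and permutes group labels; with 999 permutations the smallest
attainable p is (1+0)/(1+999) = 0.001. The implementation is cross-checked
against `vegan::adonis2` in the test suite.

**Constrained ordination.** Community matrices are Hellinger-transformed
(rows become unit-norm square-root proportions, making Euclidean methods
appropriate for counts); environmental variables are mean-imputed and then
log₁₀(x+1)-transformed — imputation strictly precedes the transform, and
every imputed cell is flagged. All variables, including temperature,
salinity and pH, receive the same transform for uniformity. Collinearity
screening removes the largest-VIF variable iteratively until all
VIF = 1/(1−R²) ≤ 10, ties breaking by column order. Redundancy analysis is
ordinary multivariate least squares followed by an eigendecomposition of
the fitted values; adjusted R² uses the Ezekiel correction. Forward
selection implements the `ordiR2step` double stopping rule: the candidate
with the largest adjusted R² is admitted only if its marginal permutation
p ≤ α (residual permutation of the reduced model) *and* the cumulative
adjusted R² does not exceed the full-model adjusted R². A consequence
worth knowing: when exactly one variable is informative and the rest are
noise, the single-variable and full-model adjusted R² converge, and the
scope rule can legitimately block selection — the two-sided nature of this
rule is inherited from the reference implementation, which the test suite
cross-checks on identical data. RDA can run at genus level (ASVs
aggregated by lineage; unclassified genera pooled per family) to match how
ordination biplots are usually drawn.

**Networks.** Surface samples of each region are analysed separately
(BR n = 6, NR n = 9 under the default design). Within each region and
marker, ASVs need mean relative abundance strictly above 0.01% and
prevalence strictly above 20%; the two markers' relative-abundance
matrices are then concatenated (each normalized within its own marker,
since 16S and 18S library depths are not comparable) and Spearman
correlations computed with mid-ranks. Edge p-values use the t
approximation t = ρ√((n−2)/(1−ρ²)); |ρ| = 1 maps to p = 0. Edges require
|ρ| > 0.6 *and* p < 0.05, both strict, on raw p-values by default
(Benjamini–Hochberg behind a flag). Isolated nodes are removed: reported
node counts mean *connected* nodes. Community detection is fast greedy
(Clauset–Newman–Moore) on |ρ| weights — modularity is undefined for
negative weights, so signs are annotations, not inputs. One
implementation subtlety: igraph's `cluster_fast_greedy` returns the
partition where greedy merging stops, which on dense graphs can sit below
the maximum-modularity cut on its own merge path (a single 4-clique ends
at a 3+1 split with Q = −0.125); `fast_greedy_modules()` therefore cuts
the dendrogram at the maximum-Q step, so a clique is one module with
Q = 0. Average path length averages over connected pairs only and the
diameter is the largest within-component eccentricity — with disconnected
networks any infinite-distance convention would be arbitrary, so none is
used. The clustering coefficient averages local clustering over nodes of
degree ≥ 2. Keystones are ranked by raw betweenness (Brandes), ties by
degree then node id; zero-betweenness nodes are never keystones, so a
network of disjoint cliques has an empty keystone list.

### Small-sample caveats

With n = 6 samples the attainable Spearman p-values are coarse: only
|ρ| ≥ 0.829 can reach p < 0.05, and the t approximation can differ from
the exact 720-ordering permutation p by up to ~0.03 at moderate ρ (it is
accurate near the tails where edge decisions happen, and exact at
|ρ| = 1). Consequently, thresholded networks at n ≤ 9 carry a substantial
false-edge floor — roughly the null t-tail probability times the number of
pairs — and per-node density metrics (average degree, clustering) are
dominated by that floor rather than by real associations. This is why the
pipeline's region-comparison *flag* for network complexity uses connected
node and edge counts, the quantities the planted structure actually moves;
`compare_regions()` still reports the direction of every metric
separately.

## The synthetic community generator

`simulate_community()` emulates the survey design the analysis assumes:
two regions (6 BR sites, 9 NR sites), three depth layers, paired 16S/18S
tables, environmental metadata, and a ground-truth record.

**Abundance model.** Base log-abundances are drawn from a log-normal
species-abundance distribution (sd 1.5 — a long-tailed, realistically
uneven community). Each sample applies multiplicative log-normal jitter
(sd 1.0) per taxon and draws reads by multinomial sampling at a
log-normally jittered depth. This logistic-normal–multinomial construction
was chosen over a Dirichlet-multinomial because planted modules need
*correlated* compositional noise, which the Dirichlet cannot express; the
overdispersion behaviour relevant to the abundance/prevalence filters is
equivalent.

**Bloom structure.** The first eukaryote ASV (genus *Noctiluca*) receives
a fixed expected relative-abundance share per region × layer — 96% (the
configured surface dominance), 39% and 32% down the BR water column; 20%,
31%, 21% in NR — by renormalizing the non-bloom fraction rather than
deleting taxa, so rarefaction behaviour stays realistic. Separately, each
sample carries a bloom *cell density* (cells/L), surface-concentrated in
BR (1.5×10⁴ at the BR surface, under the 3×10³ threshold everywhere else).
The distinction matters: relative dominance persists at depth (sinking
cells in a thin eukaryote community), but the environmental response is
driven by absolute density. True environmental drivers respond
multiplicatively to normalized density: with the default effects
(NH₄ = 6.3, PO₄ = 1.8, derived from the ~6.5× and ~2.7× surface
enrichments such blooms produce), BR surface ammonium is several-fold
enriched while mid-layer values barely differ between regions, as observed
in the field. A prokaryote "copiotroph responder" (genus label
*Nautella*) blooms alongside the focal taxon, recreating the strong
surface 16S community shift that accompanies red tides.

**Planted modules.** Module members share a latent per-sample factor. The
latent Pearson correlation is set to min(0.995, 1.02·2·sin(πρ_s/6)) for a
target Spearman ρ_s — Greiner's relation for bivariate normals plus a
small margin for the attenuation introduced by count sampling — so the
realized pairwise Spearman among module members meets the configured
target. Members are placed among the high-abundance ranks (below the top
five) so multinomial noise barely attenuates the correlation.

**Richness deficit.** A configurable fraction of the below-median
abundance taxa (never modules, the bloom taxon, its responder, or the
cleanup-filter targets) is set to zero expectation in all BR samples.
Drawing from the rare half of the pool is deliberate: it depresses Sobs,
Shannon and Pielou in BR without introducing a large common
renormalization factor across the remaining taxa, which would fabricate
spurious positive co-occurrence within BR.

**Missingness and filter targets.** A configurable fraction of nutrient
measurements is set missing at random to exercise mean imputation, and
small numbers of chloroplast/mitochondrial, metazoan/plant and
unclassified-phylum lineages are planted (at low abundance) so the cleanup
filters always have real work to do.

**What the generator does not emulate.** Sequencing-read error, chimeras
and denoising; phylogenetic structure among ASVs; seasonal or spatial
autocorrelation; genuine cross-domain trophic interactions (the integrated
networks' real prokaryote–eukaryote edges); and the pervasive
environmental covariance of real communities. Passing tests therefore
demonstrate that the *machinery* recovers planted structure under the
stated model — not that any particular field inference is correct.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; the pipeline fans a single
run seed out to per-stage child seeds through a fixed affine map
(`derive_seed()`), so any stage can be re-run in isolation and two runs
with the same config are byte-identical. The test suite sizes its
simulations for quick, stable statistics: type-I calibration uses 1,000
null replicates (PERMANOVA with 199 permutations on 2×8 Gaussian samples;
Wilcoxon at 20+20), driver recovery uses 100 seeded simulations at the
default survey design, module recovery 20 simulations with ARI measured on
the planted-module taxa across the 15 surface samples, and end-to-end
direction flags 20 full pipeline runs. The oracle checks are exhaustive
rather than sampled: all 720 orderings for the Spearman permutation null,
all 4,140 partitions of the 8-node bridged-cliques graph for modularity,
and naive path counting on 100 random graphs for betweenness.

## Known limitations

* Edge significance at n = 6 is threshold-limited (see the small-sample
  caveats above); network comparisons between regions of unequal sample
  count should lean on node/edge counts and module structure.
* PERMANOVA is one-factor; depth-layer structure enters only through the
  region comparison, not as a stratum or second factor.
* Forward selection inherits the reference double stopping rule, including
  its conservatism when a single variable dominates.
* Mean imputation understates environmental variance; imputed cells are
  flagged so downstream users can weigh them.
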