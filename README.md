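# bloomnet

Comparative diversity and co-occurrence network analysis of bloom-impacted
marine microbial communities.

## What problem does this solve?

Dinoflagellate blooms (e.g. *Noctiluca scintillans* red tides) reshape
coastal microbial communities: one taxon comes to dominate the 18S
community, nutrients such as ammonium and phosphate spike, rare taxa
disappear, and the web of co-occurring taxa thins out. Quantifying those
changes from paired 16S/18S amplicon surveys requires a long chain of
standard but fiddly steps, each with threshold choices that are easy to get
subtly wrong. `bloomnet` packages that chain as tested, reusable functions
for microbial ecologists comparing a bloom region (BR) against a reference
region (NR) across depth layers:

1. **Cleanup and normalization** — removal of chloroplast/mitochondria,
   metazoan/plant and phylum-unclassified ASVs; rarefaction of every sample
   to the minimum sequencing depth; shared-ASV (Venn) summaries.
2. **Diversity** — observed richness (Sobs), Shannon *H* = −Σ pᵢ ln pᵢ,
   Pielou *J* = *H*/ln S, Wilcoxon rank-sum tests; Bray–Curtis
   dissimilarity d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ), principal coordinate
   analysis, and one-factor PERMANOVA (Anderson's pseudo-F with seeded
   label permutation).
3. **Environment-constrained ordination** — log₁₀(x+1) transform with mean
   imputation, iterative VIF > 10 collinearity screening, Hellinger
   redundancy analysis, and permutation-based forward selection with the
   `ordiR2step` double stopping rule (admit a variable only when its
   marginal permutation p ≤ α *and* cumulative adjusted R² stays at or
   below the full-model adjusted R²).
4. **Co-occurrence networks** — per-region surface networks over ASVs with
   mean relative abundance > 0.01% and prevalence > 20%; edges are Spearman
   associations with |ρ| > 0.6 and p < 0.05 (t approximation); fast-greedy
   (Clauset–Newman–Moore) modules on |ρ| weights, with modularity
   Q = Σ_c (e_c/m − (d_c/2m)²); betweenness-centrality keystone ranking;
   extraction of negative-edge, all-prokaryote, and focal-genus modules;
   GraphML export.
5. **A synthetic generator** (`simulate_community()`) that plants every
   structure the analysis is meant to recover — bloom dominance, correlated
   taxon modules, true environmental drivers, a bloom-region richness
   deficit — with a ground-truth record, so the whole pipeline is testable
   without any sequencing data.

All user-facing functions take data frames (count tables are tibbles whose
first column is `sample_id`) and return tibbles or small S3 objects with
`tidy()`/`glance()`/`autoplot()` methods, so they compose with the pipe.

## Worked example

```r
library(bloomnet)

report <- run_pipeline(list(
  simulate = list(seed = 4),   # 6 BR + 9 NR sites, 3 layers, planted bloom
  seed     = 99
))
print(report)
#> Comparative bloom analysis report
#>   prok PERMANOVA: F = 2.33, R2 = 0.051, p = 0.028
#>   euk PERMANOVA: F = 10.62, R2 = 0.198, p = 0.001
#>  region n_nodes n_edges average_degree n_modules modularity
#>      BR     279    2834         20.315         4  0.4798593
#>      NR     391    4618         23.621         4  0.3778982
#>   br_lower_alpha_diversity: TRUE
#>   br_lower_network_complexity: TRUE
```

Reading the output: both markers separate the regions (PERMANOVA p of
0.028/0.001; the eukaryote effect is much larger because the planted bloom
taxon dominates BR surface samples at ~96% relative abundance). The BR
network retains fewer connected nodes and edges than the NR network, and
every alpha index is lower in BR — the two summary flags confirm the
planted "bloom lowers diversity and network complexity" direction. Mean
alpha diversity from the same report:

```r
report$alpha |>
  dplyr::summarise(sobs = mean(sobs), shannon = mean(shannon),
                   .by = c(marker, region))
#>   marker region  sobs shannon
#> 1 euk    BR      109.    1.85
#> 2 euk    NR      138.    3.01
#> 3 prok   BR      234.    3.64
#> 4 prok   NR      273.    4.13
```

Individual stages are plain functions: `filter_taxonomy()`,
`rarefy_min_depth()`, `alpha_diversity()`, `bray_curtis() |> pcoa()`,
`permanova()`, `prepare_env() |> vif_screen()`, `forward_select()`,
`network_filter()`, `spearman_matrix() |> build_network()`,
`fast_greedy_modules()`, `keystone_rank()`, `extract_modules()`,
`write_graphml()`. A YAML config with an `inputs:` block runs the same
pipeline on your own TSV tables.

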