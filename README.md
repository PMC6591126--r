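# rhizonet

Co-occurrence network analysis for root-microbiome OTU tables.

Field surveys of crop root fungi ask a structural question that single-taxon
statistics cannot answer: does management intensity change *how the
community is wired*?  rhizonet implements the full analysis chain used to
answer it — from a rarefied OTU count table to association networks,
keystone taxa and their environmental drivers — for microbial ecologists
comparing communities across treatments or management systems.

At its core is the **maximal information coefficient** (MIC).  For OTUs
`i, j` with per-sample abundances `x_i, x_j`, MIC searches all grids
`(kx, ky)` with `kx·ky ≤ B(n) = n^0.6`:

    MIC(x_i, x_j) = max over grids of  I*(x_i, x_j; kx, ky) / log2 min(kx, ky)

where `I*` is the mutual information maximised over grid cut-points (one
axis rank-equipartitioned, the other cut by dynamic programming).  MIC ∈
[0, 1] detects positive, negative and nonlinear dependence alike and is
exactly rank-invariant.  Pairs are tested against a shared permutation
null, adjusted by Benjamini–Hochberg, and pairs with `q < 0.05` become
edges.  Keystone taxa are nodes with jointly high degree, high closeness
and low betweenness (per-network defaults: degree > 10, closeness > 0.28,
betweenness < 0.18).  The surrounding pipeline covers alpha/beta diversity
(PERMANOVA, PERMDISP), indicator species (IndVal), random-model
comparison (Barabási–Albert and Erdős–Rényi nulls), per-farm network
connectivity versus an agricultural-intensity index, and random-forest
permutation importance of soil covariates for keystone abundance.  A
synthetic study generator with planted hub guilds and known ground truth
validates the whole chain.

## Worked example

Simulate a three-system survey (20 farms each, 1000 reads/sample, hubs
planted 10/2/0) and fit the co-occurrence network of the organic-like
block:

```r
library(rhizonet)

study <- simulate_study(sim_config(seed = 42))
organic <- prevalence_filter(study$otu[study$metadata$system == "organic", ], 2)
fit <- micnet(organic, study$taxonomy, mic_config(seed = 1))
fit
#> MIC co-occurrence network fit
#>   20 samples, 100 OTUs scored (4950 pairs)
#>   edges at q < 0.05: 555 on 90 nodes
#>   keystone taxa: 37
head(fit$keystones[, c("otu", "degree", "closeness", "betweenness", "order")], 3)
#>             otu degree closeness betweenness           order
#> OTU_003 OTU_003     31 0.4944444 0.057791200 Diversisporales
#> OTU_004 OTU_004     32 0.4684211 0.024506879      Glomerales
#> OTU_005 OTU_005     23 0.4278846 0.002872483  Paraglomerales
```

The fit reports the network (an igraph object), per-node centralities,
topology (diameter, mean degree, clustering coefficient, power-law fit)
and the keystone selection.  37 keystones with degrees near 30 against a
network mean degree of ~12 is the planted picture: mycorrhizal hub taxa
and their closest guild partners carrying a disproportionate share of
the associations.  The full
multi-network study — pooled meta-network, one network per system,
cross-system Kolmogorov–Smirnov comparisons, connectivity–intensity
regression and driver attribution — runs as:

```r
res <- run_pipeline(pipeline_config(simulate = sim_config(), seed = 42))
res
#> rhizonet pipeline result
#>   meta-network: 58 nodes, 97 edges
#>   conventional: 0 nodes, 0 edges, 0 keystones
#>   no_till: 7 nodes, 4 edges, 0 keystones
#>   organic: 75 nodes, 304 edges, 22 keystones
#>   connectivity ~ intensity: slope -5.504, R2 0.572, p 2.82e-12
#>   drivers: amf_colonization
```

The keystone-count gradient (organic > no-till ≥ conventional) and the
negative connectivity–intensity slope are the study's structural
signature; the per-farm connectivity values, diversity tables, indicator
species and driver report are all in `res`.

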