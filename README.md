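# microgill

Statistical pipeline for **16S rRNA transcript (activity) surveys of
fish gill microbiota**, built around the analysis chain used to
characterize Arctic char (*Salvelinus alpinus*) gill communities across
Arctic sites: count filtering and relative-activity normalization,
taxonomic aggregation, alpha diversity (Pielou evenness J = H/ln S,
Chao1 richness, Faith's phylogenetic diversity PD, with a
neighbor-joining tree builder), phylogenetic beta diversity (weighted
and unweighted UniFrac) with PCoA/NMDS ordination, permutation inference
(PERMANOVA pseudo-F with the (1+count)/(1+B) p-estimator, pairwise
PERMANOVA with BH adjustment, multivariate dispersion homogeneity,
environmental vector fitting with Bonferroni), indicator-taxon analysis
(IndVal = sqrt(A·B) with size-corrected specificity A and sensitivity B,
permutation null), and per-site signed Spearman co-activity networks
(|rho| > 0.4, FDR < 0.05) whose topology — degree DG, neighborhood
connectivity NC, closeness centrality CC — serves as a **dysbiosis
signature**: a healthy site shows a densely wired network, a dysbiotic
one low evenness and a sparse, fragmented network.

It is intended for microbial ecologists who want this chain as tested,
reusable functions rather than a one-off script pile, and it ships a
**logistic-normal community simulator with planted ground truth**
(site effects, indicator taxa, correlation modules, environmental
gradients, a dysbiotic site) so every stage is verifiable without any
raw sequence data.

## Worked example

Simulate the unbalanced five-site study design (140 fish, 2,000 ASVs,
one planted dysbiotic site) and run the chain:

```r
library(microgill)

ds  <- simulate_communities(scenario_presets("dysbiosis", seed = 1))
flt <- filter_dataset(ds$table)      # 10,000-count floor, 1e-5 activity
flt$table
#> <feature_table> 1843 features x 136 samples (raw counts)
flt$report$samples_removed
#> [1] "s001" "s066" "s079" "s137"

md   <- ds$metadata[ds$metadata$sample_id %in% sample_ids(flt$table), ]
rel  <- to_relative_activity(flt$table)
tree <- ape::keep.tip(ds$tree, feature_ids(flt$table))

# alpha diversity: the dysbiotic site (Site_4) has the lowest evenness
al  <- alpha_diversity(flt$table, tree)
grp <- md$community[match(al$sample_id, md$sample_id)]
round(tapply(al$J, grp, median, na.rm = TRUE), 3)
#> Site_1 Site_2 Site_3 Site_4 Site_5
#>  0.722  0.736  0.757  0.612  0.743

# beta diversity: sites differ strongly in weighted UniFrac space
d  <- unifrac(rel, tree)
permanova(d, setNames(md$community, md$sample_id),
          n_permutations = 9999, seed = 2)
#> PERMANOVA: pseudo-F = 12.18, R2 = 0.271, p = 0.0001 (9999 permutations)

# per-site co-activity networks at genus rank: Site_4 is disconnected
gen  <- aggregate_by_rank(rel, ds$taxonomy, "genus")
nets <- site_networks(gen, md, ds$taxonomy)
cmp  <- compare_networks(nets)
cmp$summary[c("site", "n_nodes", "n_edges", "n_positive", "n_negative")]
#>     site n_nodes n_edges n_positive n_negative
#> 1 Site_1      80     327        179        148
#> 2 Site_2      80     275        170        105
#> 3 Site_3      80     225        130         95
#> 4 Site_4      80       0          0          0
#> 5 Site_5      78     244        135        109
round(tapply(cmp$node_metrics$DG, cmp$node_metrics$site, median), 1)
#> Site_1 Site_2 Site_3 Site_4 Site_5
#>      9      9      8      0      9
```

Four samples fall under the read floor (as in the study design the
preset mirrors); the planted dysbiotic site has the lowest median
evenness (0.61 vs 0.72–0.76), the grouping by site explains 27% of the
UniFrac variance at the permutation floor p = 1e-4, and the dysbiotic
site's co-activity network is empty while the others carry hundreds of
signed edges (Kruskal–Wallis on node degree: chi-squared = 171.2,
p = 5.9e-36).

`run_pipeline(run_config(input = dir, out = outdir))` executes the whole
chain (validate → filter → aggregate → alpha → beta → IndVal → networks
→ comparison) on a dataset directory and writes TSV/JSON results plus a
manifest; `inst/cli/microgill.R` is a thin command-line wrapper
(`simulate`, `run-all`, and per-stage subcommands). The methods,
parameter choices and the simulator's design are documented in
`vignettes/gill-microbiota-pipeline.Rmd`.

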