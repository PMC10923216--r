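---
title: "Methods: diversity, indicator and co-activity network analysis of gill microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, indicator and co-activity network analysis of gill microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`microgill` implements the statistical chain used to characterize active
gill microbiota of anadromous Arctic char sampled across several Arctic
sites: 16S rRNA *transcript* (activity) count tables are filtered and
normalized, summarized by alpha diversity, compared across sites with
phylogenetic beta diversity and permutation inference, mined for
site-indicator taxa, and condensed into per-site co-activity networks
whose topology serves as a dysbiosis signature. A synthetic-community
generator with planted ground truth makes every stage testable without
raw sequence data.

This vignette documents the models, the tunable parameters, the
numerical choices, and — at some length — the design of the simulator,
because several of its choices are load-bearing for what the package's
tests do and do not demonstrate.

# The analysis chain

## Filtering and normalization

Raw tables hold nonnegative integer counts, features (ASVs) by samples.
`filter_dataset()` removes samples whose total count is below 10,000
reads, then features whose mean relative activity across the retained
samples is below 1e-5 — the thresholds of the study design this package
reproduces. Both are configurable, as is the order: the default removes
samples first, because mean relative activity is defined over the
retained samples; the alternative order is exposed for sensitivity
checks. The filter is idempotent. `to_relative_activity()` divides each
sample by its total; with rRNA transcript data the proportions measure
relative *activity*, not cell abundance, and all downstream composition
work (aggregation, networks, IndVal, UniFrac) runs on these proportions.

`aggregate_by_rank()` sums features by a taxonomy rank, pooling features
unresolved at that rank into an explicit `unassigned` bucket; per-sample
totals are conserved exactly. `heatmap_prep()` reproduces the standard
activity-heatmap recipe: drop variables with at least 50% zeros, drop
the lowest decile of interquartile ranges (the exact published rule of
the original tooling is not public; the decile cut is this package's
concretization and the quantile is configurable), Pareto-scale
(`(x - mean)/sqrt(sd)`), and cluster rows and columns with distance
`1 - Pearson` under Ward linkage (`ward.D2`).

## Alpha diversity

Per sample: Shannon entropy in nats, observed richness, Pielou evenness
`J = H / log(S_obs)` (undefined for a single observed taxon),
bias-corrected Chao1 `S_obs + F1(F1 - 1) / (2(F2 + 1))` (the classic
`F1^2 / 2F2` variant is behind a flag; Chao1 is refused on non-integer
data because the estimator is meaningless on proportions), and Faith's
phylogenetic diversity. Natural logarithms are used throughout, matching
the defaults of the R ecosystem these analyses usually run in.

Faith's PD follows the **rooted** convention: it is the total branch
length of the minimal subtree spanning the present leaves *and the
root*, so a single present leaf scores its full root-to-leaf path.
Conventions differ between implementations; this one is stated
explicitly and enforced by a brute-force branch-enumeration oracle in
the tests.

`nj_tree()` provides the neighbor-joining builder used when only a
taxon-level distance matrix is available: classical Saitou–Nei
agglomeration on the Q-criterion with the standard two-point branch
formulas. Negative branch estimates are clamped to zero with the deficit
moved to the sister branch, preserving path lengths through the join
(clamping can be disabled). The last three clusters attach to a single
trifurcating top node via the three-point formulas — this makes the
textbook three-taxon example exact — and midpoint rooting is available
when a binary root is required. On additive matrices the builder is an
exact inverse of path-distance computation, which the tests verify
against the simulator's tree metric.

## Beta diversity and permutation inference

`unifrac()` computes all variants branch-wise from a single postorder
accumulation of per-branch descendant proportions: unweighted (branch
presence/absence over the union of observed paths), weighted raw
(`sum l_b |p_A - p_B|`), and weighted normalized (divided by
`sum l_b (p_A + p_B)`). The study's main tests run on weighted
normalized UniFrac; pairwise site comparisons follow the unweighted
variant, and both are first-class.

`pcoa()` eigendecomposes the double-centered squared-distance matrix.
Weighted UniFrac need not be Euclidean, so negative eigenvalues can
appear: the default policy is drop-and-report, with proportion explained
computed over the positive spectrum; a Lingoes correction is available.
`betadisper_test()` embeds with all axes and handles the negative
(imaginary) part by the standard reduction — squared centroid distance
is the real-part distance minus the imaginary-part distance, truncated
at zero — then applies a one-way F on centroid distances with a
permutation null. Group centroids (not spatial medians) are used.

`permanova()` partitions distance-based sums of squares in the one-way
layout and permutes whole-sample labels. Every permutation p-value in
the package uses the `(1 + count)/(1 + B)` estimator, so the attainable
floor is `1/(B + 1)` — `1e-4` at the study's 9,999 permutations.
Permutation streams are drawn after sorting samples by identifier, so
results are reproducible for a given seed regardless of input row order.
Pairwise PERMANOVA runs each pair's sub-matrix and adjusts with
Benjamini–Hochberg.

NMDS delegates to `vegan::metaMDS` (monotone regression with ties
pooled, best of `n_starts` seeded random starts) — the same engine the
original analyses used; stress is Kruskal stress-1 on the 0–1 scale.
`envfit_vectors()` regresses each environmental variable on the
ordination axes; R² is the squared multiple correlation, the direction
is the unit-normalized coefficient vector, the permutation p permutes
the variable, and Bonferroni is applied across variables (matching the
study's choice for this step; everywhere else the package uses BH).
Samples missing a variable are dropped per variable and the retained n
is reported, never imputed.

## Indicator taxa

`indval_analysis()` computes, per taxon, specificity
`A = mean abundance in target / sum of per-group mean abundances` and
sensitivity `B = occurrence fraction in the target`, with
`IndVal = sqrt(A * B)`. Group *means* (not sums) are used so the
statistic is corrected for unequal site sizes — material here, where
site sizes range from 13 to 63; the sum-based classic variant is behind
a flag. The permutation null reshuffles the sample-to-group assignment
and recomputes the maximized statistic. Following the source analyses,
p-values are reported raw (no across-taxon correction) and the
conventional `IndVal > 0.5 & p < 0.05` rule is attached as a flag, not
applied destructively. Searching proper group combinations is off by
default; ties break toward smaller combinations, then lexicographically.

## Co-activity networks

Per site, `spearman_matrix()` correlates genus-level activity across the
site's samples (average ranks for ties; p from the t approximation, the
convention of the tooling this mirrors; exact permutation p available
for very small n), and `build_network()` keeps an edge iff `|rho| > 0.4`
**and** BH-adjusted `p < 0.05`, BH being applied within the site's
network only. Isolated genera stay in the node set — they carry
activity. Metrics are computed on the full network; the top-50-by-
activity restriction is an export/visualization filter only.

Node metrics: degree DG; neighborhood connectivity NC (mean degree of
neighbors, undefined for isolated nodes); closeness centrality CC as the
reciprocal of the *mean* shortest-path length to reachable nodes
(within-component convention, isolated nodes score 0; a variant
normalized by the reachable fraction is available). Cross-site
comparisons pool node-level metrics and apply Kruskal–Wallis with BH
pairwise Wilcoxon — treating nodes as observations, as the source
analyses do; this is pseudo-replication in the strict sense, and is
reported as the field's convention rather than a defensible sampling
model.

## Fish condition

`fulton_index()` returns `K = 100 W / L^3` (weight in g, fork length in
cm). Some reports print the algebraically different `100 (W/L)^3`; that
form is inconsistent with the usual healthy value near 1.1 and is
available only behind `as_printed = TRUE`.

# The synthetic-community generator

`simulate_communities()` draws, per sample, taxon log-activities
`eta = site mean + factor loadings x latent factors + noise`, maps them
through a softmax to proportions, and draws multinomial counts at a
lognormal depth. The logistic-normal construction (rather than a
Dirichlet) is deliberate: planted correlation structure, including
negative edges, is the point. All randomness derives from one root seed
through fixed per-component sub-streams, so adding a component never
perturbs the others and identical configs give byte-identical datasets.

Compositional data couple all taxa through the softmax denominator. Four
generator choices keep that coupling *below* the network edge threshold
in the null scenarios — and each was forced by a concrete failure mode
observed while constructing the presets:

* **Bounded factors.** Module factors are uniform with unit variance
  rather than Gaussian. A Gaussian tail event can multiply a module's
  total activity share by two orders of magnitude in one sample, and
  that one sample's denominator swing correlates every pair of taxa.
  Because the factor is non-Gaussian, the loading for a target Spearman
  rho is obtained by inverting a Monte-Carlo-tabulated loading-to-rho
  map (2e6 draws per grid point, embedded as a constant table).
* **Low-share planting.** Module and indicator taxa receive negative
  baseline offsets (`module_boost`, `indicator_offset`). A high-share
  genus toggling on and off by site would drag every other genus's
  relative activity with it, manufacturing spurious site indicators; a
  high-share module would partly cancel its own planted correlation
  through the denominator.
* **A dominance cap.** Per site, mean log-activities are tempered until
  no genus's expected share exceeds `max_expected_share` (default 0.2).
  Without it, an occasional lognormal tail genus holds most of a site's
  activity, and its sample-to-sample noise generates a dense spurious
  network precisely where the design plants a sparse one.
* **Strain-turnover site effects.** With
  `site_effect_centering = "genus"`, per-taxon site effects are
  multiplicatively re-centered inside each genus so the genus's expected
  share is exactly site-invariant: sites then differ by which strains
  (ASVs) of a genus are active — the replacement of psychrophilic by
  mesophilic strains along a temperature gradient is the biological
  template — which UniFrac and ordination see clearly while genus-level
  indicator statistics see only the explicitly planted indicators.

The dysbiotic site is produced by suppressing a random 75% of taxa by
4 log-units and mildly stretching the remaining spread: low evenness and
richness through collapse onto a moderate number of survivors, not
through one dominant taxon (see the cap above). Its network is sparse
because no correlation modules are planted there.

## Presets

* `null` — 5 sites x 10 samples, 300 taxa, no site effect, no plantings.
  The exchangeable scenario for type-I-error calibration.
* `biogeography` — 5 balanced sites (n = 20), 300 taxa in 30 genera,
  site effect 1.2 sigma entirely along a one-dimensional gradient with
  within-genus centering, three planted indicator genera per site
  (fold-change 4, prevalence 0.9, low-share), two four-genus correlation
  modules, and environmental variables loaded on the gradient. Planting
  half the genera as indicators mirrors the proportions of the original
  phylum-level indicator table and is what keeps chance flags (which are
  irreducibly about 5% of the unplanted taxa under raw p < 0.05) a small
  fraction of the flagged set.
* `dysbiosis` — the unbalanced study design (63/25/13/24/15 samples at
  five sites, 140 total, 4 samples forced below the 10,000-count floor),
  2,000 taxa in 80 genera, seven ten-genus modules (|rho| = 0.8, 3 of 10
  loadings negative) wired densely at the first site, moderately at
  three others, and absent at the fourth — the planted dysbiotic site,
  which also carries the suppression-based evenness collapse.

## What the simulator does and does not emulate

It emulates heavy-tailed compositions, variable lognormal sequencing
depth with an exact low-depth fraction, site-driven differentiation,
environmental covariates tied to a site gradient, planted indicator
taxa, per-site correlation structure with negative edges, and fish
morphometrics consistent with a healthy condition index (K about 1.13).
It does **not** emulate sequencing error, chimeras or contamination,
phylogenetic signal in abundances (the tree is independent of the
abundance model), overdispersion beyond the logistic-normal, temporal or
host-individual structure, or real taxon names — lineages are synthetic
(`Phylum_01 ... Genus_003`) by design, to avoid fake biology in
fixtures. Passing recovery tests therefore demonstrates correctness of
the statistical machinery under a known generative model, not
performance on real gill communities.

# Numerical conventions

* Permutation p-values: `(1 + count)/(1 + B)`; floor `1/(B + 1)`;
  streams drawn over identifier-sorted samples.
* BH is used for all multiple-comparison adjustment except envfit
  (Bonferroni, following the source chain); BH for networks is per site.
* PCoA eigen-tolerance: eigenvalues within `max|lambda| * 1e-9` of zero
  are treated as null axes.
* Ties: Spearman uses average ranks; top-n selection and IndVal
  best-group selection break ties lexicographically (smaller combination
  first) so results are deterministic.
* Degenerate inputs fail loudly: empty samples in normalization and
  UniFrac, all-zero distance matrices in PERMANOVA, constant variables
  in correlation screens and envfit (warned and reported as NA).

# Problem sizes in the test suite

The suite verifies oracle equivalence on 50 random 8-leaf trees
(UniFrac, Faith PD, to 1e-12), NJ inversion on 100 random 5–10-leaf
trees (1e-9), PERMANOVA against exhaustive enumeration of all 720
relabelings of a 6-sample design and against a 500-replicate null
calibration at B = 199, envfit against closed-form OLS and a
500-replicate null, indicator recovery and network precision/recall over
20 generator replicates each, and the full dysbiosis signature
end-to-end over 20 replicates of the 140-sample design. These sizes keep
the whole suite under a minute on a laptop while leaving the Monte-Carlo
bands (e.g. rejection rate 0.03–0.07 at alpha = 0.05) meaningful.

# Known limitations

* Thresholded Spearman networks on compositional data remain subject to
  closure artifacts in regimes the generator deliberately avoids
  (extreme dominance, very-high-share correlated blocks); on real data a
  compositionally aware method (e.g. SparCC-family) is the robust
  choice. The package reproduces the study's method, not the state of
  the art.
* The permutation tests assume exchangeability of samples across groups
  under the null; environmental gradients confounded with sites make
  "site" tests tests of everything that varies with site.
* Node-level network comparisons treat nodes as independent
  observations (see above).
* Faith's PD and UniFrac require every table feature to be a tree tip;
  the permissive validator subsets to the intersection and says so,
  which changes totals relative to the unfiltered table.
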