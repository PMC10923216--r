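test_that("simulation is deterministic in the root seed", {
  cfg <- scenario_presets("null", seed = 42)
  d1 <- simulate_communities(cfg)
  d2 <- simulate_communities(scenario_presets("null", seed = 42))
  expect_identical(d1$table$counts, d2$table$counts)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  d3 <- simulate_communities(scenario_presets("null", seed = 43))
  expect_false(identical(d1$table$counts, d3$table$counts))
})

test_that("simulated trees are rooted, labelled, and their path metric is
           additive", {
  sim <- simulate_tree(9, seed = 7)
  expect_true(ape::is.rooted(sim$tree))
  expect_length(sim$tree$tip.label, 9)
  expect_gt(sum(sim$tree$edge.length), 0)
  nj <- nj_tree(sim$distances)
  expect_equal(stats::cophenetic(nj)[rownames(sim$distances),
                                     colnames(sim$distances)],
               sim$distances, tolerance = 1e-9)
  expect_error(simulate_tree(2, seed = 1), "at least 3")
})

test_that("sequencing depths follow the configured lognormal and the
           low-depth fraction is exact", {
  cfg <- simulation_config(seed = 5, site_names = "S1",
                           samples_per_site = 500L, n_taxa = 50L,
                           asvs_per_genus = 5L)
  ds <- simulate_communities(cfg)
  depths <- colSums(ds$table$counts)
  ks <- suppressWarnings(
    stats::ks.test(log(depths), "pnorm", cfg$depth_meanlog,
                   cfg$depth_sdlog))
  expect_gt(ks$p.value, 0.01)

  cfg2 <- scenario_presets("dysbiosis", seed = 3)
  ds2 <- simulate_communities(cfg2)
  depths2 <- colSums(ds2$table$counts)
  expect_identical(sum(depths2 < 10000), as.integer(round(4 / 140 * 140)))
  expect_identical(sort(ds2$truth$low_depth_samples),
                   sort(names(depths2)[depths2 < 10000]))
})

test_that("planted module Spearman correlations hit their target at large
           n", {
  cfg <- module_recovery_config(seed = 77, n_samples = 1000L)
  ds <- simulate_communities(cfg)
  gen <- aggregate_by_rank(to_relative_activity(ds$table), ds$taxonomy,
                           "genus")
  sm <- spearman_matrix(gen)
  tr <- ds$truth$edges
  rr <- mapply(function(a, b) sm$rho[a, b], tr$from, tr$to)
  expect_lt(abs(mean(abs(rr)) - 0.7), 0.05)
  expect_identical(unname(rr > 0), tr$sign == "positive")
})

test_that("config validation rejects inconsistent plantings", {
  expect_error(simulation_config(
    seed = 1, site_names = c("A", "B"), samples_per_site = c(5L, 5L),
    n_taxa = 20L, asvs_per_genus = 2L,
    indicator_spec = list(list(genus = "Genus_001", site = "A",
                               fold_change = 4, prevalence = 0.9)),
    module_spec = list(list(genera = c("Genus_001", "Genus_002"),
                            loadings = c(1, -1), target_rho = 0.5))),
    "both as indicator and in a module")
  expect_error(simulation_config(seed = 1, samples_per_site = rep(5L, 5),
                                 n_taxa = 10L, fraction_low_depth = 1.2))
  expect_error(scenario_presets("volcano"))
})

test_that("presets encode the study conditions and write/read round-trip", {
  dys <- scenario_presets("dysbiosis", seed = 1)
  expect_setequal(dys$samples_per_site, c(63L, 25L, 13L, 24L, 15L))
  expect_identical(sum(dys$samples_per_site), 140L)
  expect_gte(dys$n_taxa, 1000L)
  expect_identical(length(dys$module_spec[[1]]$genera), 10L)
  nul <- scenario_presets("null", seed = 1)
  expect_identical(nul$site_effect_size, 0)
  expect_length(nul$indicator_spec, 0)
  expect_length(nul$module_spec, 0)

  ds <- simulate_communities(scenario_presets("biogeography", seed = 2))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  tab <- read_feature_table(file.path(dir, "counts.tsv"))
  expect_identical(tab$counts, ds$table$counts + 0)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(md$community, ds$metadata$community)
  tr <- read_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, feature_ids(ds$table))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(nrow(truth$indicators), nrow(ds$truth$indicators))
})

test_that("the biogeography preset's gradient is recoverable: PERMANOVA at
           the permutation floor, envfit R2 above 0.5", {
  r2 <- vapply(1:3, function(seed) {
    ds <- simulate_communities(scenario_presets("biogeography",
                                                seed = seed))
    flt <- filter_dataset(ds$table)
    md <- ds$metadata[ds$metadata$sample_id %in% sample_ids(flt$table), ]
    rel <- to_relative_activity(flt$table)
    tree <- ape::keep.tip(ds$tree, feature_ids(flt$table))
    dw <- unifrac(rel, tree)
    groups <- setNames(md$community, md$sample_id)
    pm <- permanova(dw, groups, 999, seed = seed)
    expect_equal(pm$p_value, 1 / 1000)
    nm <- suppressWarnings(nmds(dw, seed = seed))
    env <- md[c("sample_id", "air_temperature")]
    ef <- envfit_vectors(nm$coordinates, env, 199, seed = seed)
    ef$R2[1]
  }, numeric(1))
  expect_gt(mean(r2), 0.5)
})
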