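#' Default pipeline configuration
#'
#' All thresholds default to the study parameterization: sample floor
#' 10,000 counts, feature floor 1e-5 mean relative activity, genus rank for
#' aggregation and networks, weighted UniFrac for the main PERMANOVA /
#' PCoA / NMDS and unweighted for the pairwise tests, 9,999 permutations,
#' Spearman edge threshold 0.4 at FDR 0.05, IndVal threshold 0.5.
#'
#' @param input directory containing `counts.tsv`, `taxonomy.tsv`,
#'   `metadata.tsv`, `tree.nwk` (as written by [write_dataset()]), or a
#'   named list of the four paths.
#' @param out output directory.
#' @param ... overrides for any default listed below.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(input, out, ...) {
  cfg <- list(
    input = input, out = out,
    min_sample_total = 10000, min_mean_relative = 1e-5,
    filter_order = "samples_first",
    rank = "genus", top_n = 50,
    main_distance = "weighted_unifrac",
    pairwise_distance = "unweighted_unifrac",
    n_permutations = 9999, seed = 1,
    network_threshold = 0.4, network_alpha = 0.05,
    network_min_samples = 4,
    indval_threshold = 0.5, indval_alpha = 0.05,
    env_variables = c("air_temperature", "water_temperature", "salinity",
                      "pH", "chlorophyll_a", "O2_concentration"),
    nmds_k = 2, nmds_starts = 20
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' The file must provide `input` and `out`; any other key overrides the
#' [run_config()] default of the same name (unknown keys are an error).
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$input) || is.null(raw$out)) {
    stop("config must provide 'input' and 'out'")
  }
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: validate, filter, aggregate, alpha diversity, beta
#' diversity (UniFrac, PCoA, PERMANOVA, pairwise PERMANOVA, dispersion,
#' NMDS, envfit), indicator analysis, per-site networks, cross-site
#' comparison. Every result is written under `config$out` together with a
#' manifest (stage timings, warnings, input checksums, config hash); a
#' stage failure halts the run but leaves earlier outputs and the manifest
#' intact.
#'
#' @param config a `run_config` (or path to one, see [read_run_config()]).
#' @return the output directory, invisibly; the manifest is
#'   `<out>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = paste0("microgill ", as.character(utils::packageVersion("microgill"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, stages = list()
  )
  cfg_path <- file.path(out, "run_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  paths <- if (is.list(config$input)) config$input else list(
    counts = file.path(config$input, "counts.tsv"),
    taxonomy = file.path(config$input, "taxonomy.tsv"),
    metadata = file.path(config$input, "metadata.tsv"),
    tree = file.path(config$input, "tree.nwk")
  )
  needs_tree <- TRUE  # UniFrac + Faith PD are always on the main path
  if (needs_tree && !file.exists(paths$tree)) {
    stop("tree required for UniFrac/Faith PD but not found: ", paths$tree)
  }
  manifest$input_checksums <- lapply(paths, function(p)
    unname(tools::md5sum(p)))

  finish <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    res <- tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$stages[[name]] <<- list(status = "error",
                                         message = conditionMessage(e))
        finish()
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      warnings = warns)
    res
  }

  ds <- stage("validate", {
    tb <- read_feature_table(paths$counts)
    tx <- read_taxonomy(paths$taxonomy)
    md <- read_metadata(paths$metadata)
    tr <- read_tree(paths$tree)
    validate_dataset(tb, tx, md, tr, strict = FALSE)
  })

  flt <- stage("filter", {
    res <- filter_dataset(ds$table,
                          min_sample_total = config$min_sample_total,
                          min_mean_relative = config$min_mean_relative,
                          order = config$filter_order)
    jsonlite::write_json(res$report, file.path(out, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res
  })
  table <- flt$table
  tree <- ape::keep.tip(ds$tree, feature_ids(table))
  metadata <- ds$metadata[ds$metadata$sample_id %in% sample_ids(table), ]
  rel <- to_relative_activity(table)

  genus_rel <- stage("aggregate", {
    g <- aggregate_by_rank(rel, ds$taxonomy, config$rank)
    write_feature_table(g, file.path(out, "aggregated_relative.tsv"),
                        id_column = config$rank)
    g
  })

  alpha <- stage("alpha", {
    res <- alpha_pipeline(table, tree, metadata)
    utils::write.table(res$per_sample, file.path(out, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(res$tests, function(t) list(chi_squared = t$statistic,
                                         df = t$df, p = t$p_value,
                                         pairwise_bh = as.data.frame(t$pairwise))),
      file.path(out, "alpha_tests.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    res
  })

  beta <- stage("beta", {
    groups <- stats::setNames(metadata$community, metadata$sample_id)
    d_w <- unifrac(rel, tree, weighted = TRUE, normalized = TRUE)
    d_u <- unifrac(rel, tree, weighted = FALSE)
    write_distance_matrix(d_w, file.path(out, "weighted_unifrac.tsv"))
    write_distance_matrix(d_u, file.path(out, "unweighted_unifrac.tsv"))
    pick <- function(tag) switch(tag,
      weighted_unifrac = d_w, unweighted_unifrac = d_u,
      stop("unknown distance variant: ", tag))
    d_main <- pick(config$main_distance)
    ord <- pcoa(d_main)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      file.path(out, "pcoa_coordinates.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    pm <- permanova(d_main, groups, config$n_permutations,
                    seed = config$seed)
    pw <- pairwise_permanova(pick(config$pairwise_distance), groups,
                             config$n_permutations, seed = config$seed + 1)
    bd <- betadisper_test(d_main, groups, config$n_permutations,
                          seed = config$seed + 2)
    nm <- nmds(d_main, k = config$nmds_k, n_starts = config$nmds_starts,
               seed = config$seed + 3)
    env <- metadata[c("sample_id",
                      intersect(config$env_variables, names(metadata)))]
    ef <- envfit_vectors(nm$coordinates, env, config$n_permutations,
                         seed = config$seed + 4)
    utils::write.table(ef, file.path(out, "envfit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      pcoa_proportion_explained = ord$proportion_explained,
      pcoa_negative_eigenvalues = ord$negative_eigenvalues,
      permanova = list(pseudo_F = pm$pseudo_F, R2 = pm$R2, p = pm$p_value,
                       permutations = pm$n_permutations,
                       distance = config$main_distance),
      pairwise_permanova = pw,
      betadisper = list(F = bd$F, p = bd$p_value),
      nmds_stress = nm$stress
    ), file.path(out, "beta_tests.json"), auto_unbox = TRUE, digits = NA,
       pretty = TRUE)
    list(d_w = d_w, d_u = d_u, ord = ord, permanova = pm, pairwise = pw,
         betadisper = bd, nmds = nm, envfit = ef)
  })

  indval <- stage("indval", {
    groups <- stats::setNames(metadata$community, metadata$sample_id)
    res <- indval_analysis(genus_rel, groups,
                           n_permutations = min(config$n_permutations, 999),
                           seed = config$seed + 5,
                           indval_threshold = config$indval_threshold,
                           alpha = config$indval_alpha)
    utils::write.table(res, file.path(out, "indval.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  networks <- stage("networks", {
    nets <- site_networks(genus_rel, metadata, ds$taxonomy,
                          threshold = config$network_threshold,
                          alpha = config$network_alpha,
                          min_samples = config$network_min_samples)
    for (site in names(nets)) {
      export_network(nets[[site]],
                     file.path(out, paste0("network_", site, ".tsv")),
                     format = "edgelist")
      export_network(nets[[site]],
                     file.path(out, paste0("network_", site, ".graphml")),
                     format = "graphml", top_n = config$top_n)
    }
    nets
  })

  comparison <- stage("compare", {
    cmp <- compare_networks(networks)
    utils::write.table(cmp$node_metrics,
                       file.path(out, "node_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$summary, file.path(out, "network_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(cmp$tests, function(t) if (is.null(t)) NULL else
        list(chi_squared = t$statistic, df = t$df, p = t$p_value)),
      file.path(out, "network_tests.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    cmp
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  finish()
  invisible(out)
}
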