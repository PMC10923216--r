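#' Simulation configuration for synthetic gill-community datasets
#'
#' The generator draws per-sample taxon log-activities from a
#' logistic-normal model — site mean + latent-factor modules + independent
#' noise, softmax to proportions, multinomial counts at lognormal depth —
#' so that site differentiation, indicator taxa, environmental gradients
#' and per-site correlation structure (including negative edges) can all be
#' planted with known ground truth. Logistic-normal rather than Dirichlet
#' because planted correlation structure is the point; the weak spurious
#' negative correlation induced by compositional closure stays far below
#' the 0.4 edge threshold at the default taxon counts.
#'
#' @param seed integer root seed; all component sub-streams derive from it.
#' @param site_names site labels.
#' @param samples_per_site integer vector, one entry per site (may be
#'   unbalanced, as in the 63/25/13/24/15 study design).
#' @param n_taxa number of features (ASVs).
#' @param asvs_per_genus features per genus; genera are the network/
#'   indicator planting unit.
#' @param depth_meanlog,depth_sdlog lognormal sequencing-depth parameters
#'   (counts).
#' @param fraction_low_depth fraction of samples forced below the 10,000
#'   count floor (exact by construction: `round(fraction * N)` samples get
#'   a uniform depth in `[2000, 9999]`; the rest are redrawn above the
#'   floor).
#' @param site_effect_size shift of site mean log-activity, in units of the
#'   baseline log-activity noise (0 = exchangeable null).
#' @param gradient_frac fraction of the site effect aligned with the
#'   one-dimensional environmental gradient (the rest is site-idiosyncratic).
#' @param site_effect_centering `"none"` (default) or `"genus"`: with
#'   `"genus"`, per-taxon site effects are centered within each genus, so
#'   sites differ by strain (ASV) turnover inside genera — the
#'   psychrophilic-to-mesophilic replacement pattern seen along
#'   temperature gradients — while genus totals stay nearly flat. This
#'   yields strong phylogenetic (UniFrac) differentiation without turning
#'   every genus into a site indicator.
#' @param noise_sd per-sample, per-taxon log-activity noise sd.
#' @param abundance_sd sd of baseline log-activities (heavy-tailed
#'   compositions).
#' @param evenness_scale scalar or named per-site vector; values above 1
#'   stretch the site's log-activity spread, lowering evenness (the
#'   dysbiosis lever).
#' @param max_expected_share per-site ceiling on any single taxon's
#'   expected activity share. Site mean vectors are tempered iteratively
#'   until the softmax share of every taxon falls below the ceiling:
#'   extreme single-taxon dominance would make every other taxon's
#'   relative activity track the dominant taxon's noise through the
#'   common denominator, degenerating correlation networks.
#' @param site_suppression named list, site -> `list(fraction, shift)`:
#'   a random `fraction` of taxa get `shift` subtracted from that site's
#'   mean log-activity. Suppressing most taxa concentrates activity on the
#'   survivors — the low-evenness, low-richness profile of a dysbiotic
#'   community — without handing the whole community to a single dominant
#'   taxon (whose sample-to-sample noise would couple all other taxa
#'   through the softmax denominator).
#' @param indicator_spec list of `list(genus, site, fold_change, prevalence)`;
#'   member features get `log(fold_change)` added to the target site mean
#'   and Bernoulli(`prevalence`) occupancy there
#'   (`indicator_background_prevalence` elsewhere).
#' @param module_spec list of
#'   `list(genera, loadings, target_rho, sites)`; `loadings` is a +/-1 sign
#'   pattern per genus, `target_rho` the planted pairwise |Spearman| among
#'   member taxa (the factor loading inverts a Monte-Carlo-tabulated
#'   loading-to-Spearman map for the bounded-factor model),
#'   `sites = NULL` means all sites.
#' @param env_spec named list of `list(mean, loading, noise_sd)` per
#'   environmental variable; the variable equals
#'   `mean + loading * u_site + noise`, with `u` the standardized site
#'   gradient.
#' @param module_boost baseline log-activity offset applied to module
#'   genera. Negative values keep the modules' total activity share small,
#'   which both preserves the planted correlation (a dominant block partly
#'   cancels its own shared factor through the softmax denominator) and
#'   avoids coupling unrelated taxa through that denominator.
#' @param indicator_background_prevalence occupancy of indicator taxa
#'   outside their target site.
#' @param indicator_offset baseline log-activity offset of indicator taxa.
#'   Kept negative so indicators are minor community members: a
#'   high-share taxon switching on and off by site would drag every other
#'   taxon's relative activity with it through the common denominator,
#'   turning unrelated taxa into spurious site indicators.
#' @return validated object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              site_names = paste0("Site_", 1:5),
                              samples_per_site = rep(10L, 5),
                              n_taxa = 300L,
                              asvs_per_genus = 4L,
                              depth_meanlog = log(30000),
                              depth_sdlog = 0.5,
                              fraction_low_depth = 0,
                              site_effect_size = 0,
                              gradient_frac = 0.6,
                              site_effect_centering = c("none", "genus"),
                              noise_sd = 1,
                              abundance_sd = 2,
                              evenness_scale = 1,
                              max_expected_share = 0.2,
                              site_suppression = list(),
                              indicator_spec = list(),
                              module_spec = list(),
                              env_spec = default_env_spec(),
                              module_boost = 0,
                              indicator_background_prevalence = 0.15,
                              indicator_offset = -2) {
  stopifnot(length(samples_per_site) == length(site_names),
            all(samples_per_site >= 1), n_taxa >= 3, asvs_per_genus >= 1,
            fraction_low_depth >= 0, fraction_low_depth < 1,
            site_effect_size >= 0, noise_sd > 0, abundance_sd > 0,
            gradient_frac >= 0, gradient_frac <= 1)
  site_effect_centering <- match.arg(site_effect_centering)
  if (length(evenness_scale) == 1L) {
    evenness_scale <- stats::setNames(rep(evenness_scale,
                                          length(site_names)), site_names)
  }
  stopifnot(all(site_names %in% names(evenness_scale)),
            all(evenness_scale > 0))
  for (sp in site_suppression) {
    stopifnot(sp$fraction > 0, sp$fraction < 1, sp$shift > 0)
  }
  stopifnot(all(names(site_suppression) %in% site_names))
  stopifnot(max_expected_share > 1 / n_taxa, max_expected_share <= 1)
  for (ind in indicator_spec) {
    stopifnot(!is.null(ind$genus), ind$site %in% site_names,
              ind$fold_change > 1,
              ind$prevalence > 0, ind$prevalence <= 1)
  }
  module_genera <- character(0)
  for (mod in module_spec) {
    stopifnot(length(mod$genera) >= 2,
              length(mod$loadings) == length(mod$genera),
              all(abs(mod$loadings) == 1),
              mod$target_rho > 0, mod$target_rho < 1,
              is.null(mod$sites) || all(mod$sites %in% site_names))
    module_genera <- c(module_genera, mod$genera)
  }
  clash <- intersect(module_genera,
                     vapply(indicator_spec, `[[`, "", "genus"))
  if (length(clash)) {
    stop("genus planted both as indicator and in a module: ",
         paste(clash, collapse = ", "))
  }
  structure(list(seed = seed, site_names = site_names,
                 samples_per_site = as.integer(samples_per_site),
                 n_taxa = as.integer(n_taxa),
                 asvs_per_genus = as.integer(asvs_per_genus),
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 fraction_low_depth = fraction_low_depth,
                 site_effect_size = site_effect_size,
                 gradient_frac = gradient_frac,
                 site_effect_centering = site_effect_centering,
                 noise_sd = noise_sd, abundance_sd = abundance_sd,
                 evenness_scale = evenness_scale,
                 max_expected_share = max_expected_share,
                 site_suppression = site_suppression,
                 indicator_spec = indicator_spec,
                 module_spec = module_spec, env_spec = env_spec,
                 module_boost = module_boost,
                 indicator_background_prevalence =
                   indicator_background_prevalence,
                 indicator_offset = indicator_offset),
            class = "simulation_config")
}

# Spearman correlation between lambda*f + e1 and lambda*f + e2 with f
# uniform on [-sqrt(3), sqrt(3)] and e ~ N(0,1), tabulated by Monte Carlo
# (2e6 draws per grid point); monotone-interpolated to invert target
# Spearman -> factor loading. Scale-free in lambda/noise_sd.
MODULE_RHO_TABLE <- list(
  lambda = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.1, 1.2,
             1.3, 1.4, 1.5, 1.75, 2, 2.25, 2.5, 2.75, 3, 3.25, 3.5, 3.75,
             4, 5, 6),
  rho = c(0, 0.0098, 0.0374, 0.0806, 0.1357, 0.1987, 0.2655, 0.3325,
          0.3972, 0.4578, 0.5132, 0.5631, 0.6074, 0.6465, 0.681, 0.7112,
          0.7716, 0.8158, 0.8487, 0.8737, 0.8931, 0.9084, 0.9207, 0.9307,
          0.9389, 0.9458, 0.9642, 0.9747)
)

# temper a mean log-activity vector until no genus's softmax share
# exceeds `cap` (see max_expected_share); the genus is the aggregation
# unit of the downstream correlation networks, so the cap binds there
cap_dominance <- function(m, cap, genus) {
  for (it in 1:10) {
    p <- exp(m - max(m))
    p <- p / sum(p)
    pg <- rowsum(p, genus)
    over_g <- rownames(pg)[pg[, 1L] > cap]
    if (!length(over_g)) break
    over <- genus %in% over_g
    excess <- (pg[genus, 1L] / cap)[over]
    m[over] <- m[over] - log(excess) - 0.02
  }
  m
}

module_loading <- function(target_rho) {
  stopifnot(target_rho > 0, target_rho <= max(MODULE_RHO_TABLE$rho))
  stats::approx(MODULE_RHO_TABLE$rho, MODULE_RHO_TABLE$lambda,
                xout = target_rho)$y
}

default_env_spec <- function() {
  list(
    air_temperature = list(mean = 5, loading = 8, noise_sd = 2),
    water_temperature = list(mean = 5, loading = 4, noise_sd = 1.5),
    salinity = list(mean = 15, loading = -10, noise_sd = 3),
    pH = list(mean = 7.8, loading = 0.3, noise_sd = 0.2),
    chlorophyll_a = list(mean = 2, loading = 1, noise_sd = 0.5),
    O2_concentration = list(mean = 10, loading = -2, noise_sd = 1)
  )
}

#' Simulate a random rooted tree over taxa
#'
#' Random bifurcating topology (sequential random joins via `ape::rtree`)
#' with exponential branch lengths; also returns the tree's path metric,
#' which is additive by construction — the neighbor-joining inversion
#' property tests feed on it.
#'
#' @param taxa tip labels (or an integer count).
#' @param seed integer seed.
#' @param branch_rate rate of the exponential branch lengths.
#' @return list with `tree` (`phylo`) and `distances` (cophenetic matrix).
#' @export
simulate_tree <- function(taxa, seed = 1, branch_rate = 5) {
  if (length(taxa) == 1L && is.numeric(taxa)) {
    taxa <- sprintf("t%03d", seq_len(taxa))
  }
  if (length(taxa) < 3) stop("need at least 3 taxa")
  set.seed(seed)
  tree <- ape::rtree(length(taxa), rooted = TRUE,
                     br = function(n) stats::rexp(n, branch_rate))
  tree$tip.label <- sample(taxa)  # decouple labels from rtree's ordering
  list(tree = tree, distances = stats::cophenetic(tree))
}

#' Simulate a complete synthetic dataset with planted truth
#'
#' Generates counts, taxonomy, metadata (environment + fish morphometrics),
#' a phylogenetic tree, and a `truth` record (site gradient, indicator
#' pairs, true module edges with signs) from a [simulation_config()]. All
#' randomness derives from the config seed through fixed per-component
#' sub-streams, so adding a component never perturbs the others and
#' identical configs give identical datasets.
#'
#' @param config a `simulation_config`.
#' @return list with `table` (raw `feature_table`), `taxonomy`, `metadata`,
#'   `tree`, `truth`, `config`.
#' @export
simulate_communities <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n_sites <- length(cfg$site_names)
  N <- sum(cfg$samples_per_site)
  site_of <- rep(cfg$site_names, cfg$samples_per_site)
  sample_ids <- sprintf("s%03d", seq_len(N))
  taxa <- sprintf("asv%04d", seq_len(cfg$n_taxa))
  n_genera <- ceiling(cfg$n_taxa / cfg$asvs_per_genus)
  genus_of <- sprintf("Genus_%03d",
                      rep(seq_len(n_genera),
                          each = cfg$asvs_per_genus)[seq_len(cfg$n_taxa)])
  n_phyla <- max(2L, min(8L, n_genera))
  phylum_idx <- ((match(genus_of, unique(genus_of)) - 1L) %% n_phyla) + 1L

  # standardized one-dimensional site gradient (e.g. latitude/temperature)
  if (n_sites > 1) {
    u <- seq(-1, 1, length.out = n_sites)
    u <- (u - mean(u)) / stats::sd(u)
  } else {
    u <- 0
  }
  names(u) <- cfg$site_names

  # --- baseline and site mean log-activities (sub-stream 2)
  set.seed(cfg$seed + 2L)
  mu0 <- stats::rnorm(cfg$n_taxa, 0, cfg$abundance_sd)
  module_taxa <- unlist(lapply(cfg$module_spec, function(m) {
    which(genus_of %in% m$genera)
  }))
  mu0[unique(module_taxa)] <- mu0[unique(module_taxa)] + cfg$module_boost
  v <- stats::rnorm(cfg$n_taxa)
  # multiplicative within-genus centering: rescale each genus's shifted
  # members so the genus's expected share (at baseline weights) is exactly
  # unchanged — the site effect then reads as strain turnover inside
  # genera, invisible to genus-level statistics
  wt <- exp(mu0 - stats::ave(mu0, genus_of, FUN = max))
  wt_sum <- stats::ave(wt, genus_of, FUN = sum)
  center <- function(delta) {
    if (!identical(cfg$site_effect_centering, "genus")) return(delta)
    gsum <- stats::ave(wt * exp(delta), genus_of, FUN = sum) / wt_sum
    delta - log(gsum)
  }
  M <- matrix(0, cfg$n_taxa, n_sites,
              dimnames = list(taxa, cfg$site_names))
  for (g in seq_len(n_sites)) {
    w_g <- stats::rnorm(cfg$n_taxa)
    delta <- cfg$site_effect_size *
      (sqrt(cfg$gradient_frac) * u[g] * v +
         sqrt(1 - cfg$gradient_frac) * w_g)
    delta <- center(delta)
    M[, g] <- cfg$evenness_scale[cfg$site_names[g]] * (mu0 + delta)
  }
  for (site in names(cfg$site_suppression)) {
    sp <- cfg$site_suppression[[site]]
    hit <- sample.int(cfg$n_taxa, round(sp$fraction * cfg$n_taxa))
    M[hit, site] <- M[hit, site] - sp$shift
  }
  for (ind in cfg$indicator_spec) {
    rows <- which(genus_of == ind$genus)
    if (!length(rows)) stop("indicator genus not present: ", ind$genus)
    M[rows, ] <- M[rows, ] + cfg$indicator_offset
    M[rows, ind$site] <- M[rows, ind$site] + log(ind$fold_change)
  }
  # cap last, so a planted indicator cannot blow past the ceiling either
  for (g in seq_len(n_sites)) {
    M[, g] <- cap_dominance(M[, g], cfg$max_expected_share, genus_of)
  }

  # --- latent-factor modules and per-sample log-activities (sub-stream 3)
  set.seed(cfg$seed + 3L)
  eta <- M[, site_of] + matrix(stats::rnorm(cfg$n_taxa * N, 0, cfg$noise_sd),
                               cfg$n_taxa, N)
  for (mod in cfg$module_spec) {
    lambda <- module_loading(mod$target_rho) * cfg$noise_sd
    in_sites <- if (is.null(mod$sites)) rep(TRUE, N) else
      site_of %in% mod$sites
    # bounded unit-variance factor: avoids single-sample blowups of the
    # module's total activity share (which would couple unrelated taxa
    # through the softmax denominator)
    f <- stats::runif(N, -sqrt(3), sqrt(3))
    load_of_taxon <- stats::setNames(mod$loadings, mod$genera)
    rows <- which(genus_of %in% mod$genera)
    eta[rows, in_sites] <- eta[rows, in_sites] +
      lambda * outer(load_of_taxon[genus_of[rows]], f[in_sites])
  }
  # indicator occupancy: Bernoulli presence, low background elsewhere
  for (ind in cfg$indicator_spec) {
    rows <- which(genus_of == ind$genus)
    prev <- ifelse(site_of == ind$site, ind$prevalence,
                   cfg$indicator_background_prevalence)
    absent <- stats::runif(N) > prev
    eta[rows, absent] <- -Inf
  }
  colnames(eta) <- sample_ids

  # --- depths (sub-stream 4): exact low-depth fraction by construction
  set.seed(cfg$seed + 4L)
  depth <- round(stats::rlnorm(N, cfg$depth_meanlog, cfg$depth_sdlog))
  n_low <- round(cfg$fraction_low_depth * N)
  if (n_low > 0) {
    low_idx <- sample.int(N, n_low)
    depth[low_idx] <- sample(2000:9999, n_low, replace = TRUE)
    high <- setdiff(seq_len(N), low_idx)
  } else {
    high <- seq_len(N)
  }
  if (cfg$fraction_low_depth > 0) {
    while (any(depth[high] < 10000)) {  # keep the split exact
      redo <- high[depth[high] < 10000]
      depth[redo] <- round(stats::rlnorm(length(redo), cfg$depth_meanlog,
                                         cfg$depth_sdlog))
    }
  }

  # --- multinomial counts (sub-stream 5)
  set.seed(cfg$seed + 5L)
  counts <- matrix(0L, cfg$n_taxa, N, dimnames = list(taxa, sample_ids))
  for (s in seq_len(N)) {
    e <- eta[, s]
    p <- exp(e - max(e[is.finite(e)]))
    p[!is.finite(p)] <- 0
    counts[, s] <- stats::rmultinom(1, depth[s], p / sum(p))
  }

  # --- environment + fish morphometrics (sub-stream 6)
  set.seed(cfg$seed + 6L)
  md <- data.frame(sample_id = sample_ids, community = site_of,
                   location = site_of,
                   water_type = rep(c("Saltwater", "Freshwater"),
                                    length.out = n_sites)[
                                      match(site_of, cfg$site_names)],
                   latitude = 58 + 11 * (u[site_of] - min(u)) /
                     max(diff(range(u)), 1e-9),
                   longitude = -105 + 10 * match(site_of, cfg$site_names),
                   stringsAsFactors = FALSE)
  for (vn in names(cfg$env_spec)) {
    sp <- cfg$env_spec[[vn]]
    md[[vn]] <- sp$mean + sp$loading * u[site_of] +
      stats::rnorm(N, 0, sp$noise_sd)
  }
  L <- stats::rnorm(N, 45, 4)
  K <- stats::rnorm(N, 1.13, 0.08)
  md$fork_length <- round(L, 1)
  md$weight <- round(K * L^3 / 100, 1)

  # --- tree (sub-stream 1)
  tr <- simulate_tree(taxa, seed = cfg$seed + 1L)

  taxonomy <- data.frame(
    feature_id = taxa,
    kingdom = "Bacteria_synth",
    phylum = sprintf("Phylum_%02d", phylum_idx),
    class = sprintf("Class_%02d", phylum_idx),
    order = sprintf("Order_%02d", phylum_idx),
    family = sprintf("Family_%03d", match(genus_of, unique(genus_of))),
    genus = genus_of,
    species = paste0(genus_of, "_sp"),
    stringsAsFactors = FALSE
  )

  true_edges <- do.call(rbind, lapply(cfg$module_spec, function(mod) {
    pr <- utils::combn(seq_along(mod$genera), 2L)
    data.frame(
      from = pmin(mod$genera[pr[1L, ]], mod$genera[pr[2L, ]]),
      to = pmax(mod$genera[pr[1L, ]], mod$genera[pr[2L, ]]),
      sign = ifelse(mod$loadings[pr[1L, ]] * mod$loadings[pr[2L, ]] > 0,
                    "positive", "negative"),
      rho = mod$target_rho,
      sites = paste(if (is.null(mod$sites)) cfg$site_names else mod$sites,
                    collapse = "+"),
      stringsAsFactors = FALSE
    )
  }))
  truth <- list(
    gradient = u,
    site_means = M,
    indicators = do.call(rbind, lapply(cfg$indicator_spec, function(ind) {
      data.frame(genus = ind$genus, site = ind$site,
                 fold_change = ind$fold_change,
                 prevalence = ind$prevalence, stringsAsFactors = FALSE)
    })),
    edges = true_edges,
    env_loadings = vapply(cfg$env_spec, `[[`, 0, "loading"),
    low_depth_samples = sample_ids[depth < 10000]
  )

  list(table = feature_table(counts), taxonomy = taxonomy, metadata = md,
       tree = tr$tree, truth = truth, config = cfg)
}

#' Named simulation presets
#'
#' Three documented study conditions:
#' \itemize{
#'   \item `"null"` — 5 sites x 10 samples, no site effect, no indicators,
#'     no modules; the exchangeable scenario used for type-I calibration.
#'   \item `"biogeography"` — 5 balanced sites (n = 20), moderate
#'     gradient-aligned site effect, one planted indicator genus per site
#'     (fold-change 4, prevalence 0.9), two all-site correlation modules,
#'     environmental variables loaded on the gradient.
#'   \item `"dysbiosis"` — the unbalanced study design (n = 63/25/13/24/15
#'     across 5 sites), thousands of features, a densely wired "resilient"
#'     first site, moderately wired middle sites, and a fourth site with no
#'     correlation modules and stretched log-activity spread (low evenness):
#'     the planted dysbiotic community. A small fraction of samples falls
#'     under the 10,000-count floor, as in the study.
#' }
#'
#' @param name preset name.
#' @param seed root seed.
#' @return a [simulation_config()].
#' @export
scenario_presets <- function(name = c("null", "biogeography", "dysbiosis"),
                             seed = 1) {
  name <- match.arg(name)
  if (name == "null") {
    return(simulation_config(seed = seed, n_taxa = 300L,
                             samples_per_site = rep(10L, 5),
                             site_effect_size = 0))
  }
  if (name == "biogeography") {
    genera <- sprintf("Genus_%03d", 1:30)
    indicators <- lapply(1:15, function(k) {
      list(genus = genera[k], site = paste0("Site_", (k - 1) %% 5 + 1),
           fold_change = 4, prevalence = 0.9)
    })
    modules <- list(
      list(genera = genera[16:19], loadings = c(1, 1, 1, -1),
           target_rho = 0.7, sites = NULL),
      list(genera = genera[20:23], loadings = c(1, -1, 1, 1),
           target_rho = 0.7, sites = NULL)
    )
    return(simulation_config(seed = seed, n_taxa = 300L,
                             asvs_per_genus = 10L,
                             samples_per_site = rep(20L, 5),
                             site_effect_size = 1.2,
                             gradient_frac = 1,
                             site_effect_centering = "genus",
                             abundance_sd = 1.2,
                             module_boost = -1,
                             indicator_spec = indicators,
                             indicator_offset = -3,
                             module_spec = modules))
  }
  # dysbiosis: unbalanced study design, Site_4 is the planted dysbiotic site
  n_genera <- 80L
  genera <- sprintf("Genus_%03d", seq_len(n_genera))
  module_sets <- split(1:70, rep(1:7, each = 10))  # genera 1..70, 7 blocks
  site_modules <- list(Site_1 = 1:7, Site_2 = 1:5, Site_3 = 2:6,
                       Site_4 = integer(0), Site_5 = 3:7)
  modules <- list()
  for (site in names(site_modules)) {
    for (k in site_modules[[site]]) {
      idx <- module_sets[[k]]
      modules <- c(modules, list(list(
        genera = genera[idx],
        loadings = c(1, 1, 1, 1, 1, 1, 1, -1, -1, -1),
        target_rho = 0.8,
        sites = site
      )))
    }
  }
  indicators <- lapply(1:5, function(g) {
    list(genus = genera[75 + g], site = paste0("Site_", g),
         fold_change = 4, prevalence = 0.9)
  })
  simulation_config(seed = seed, n_taxa = 2000L, asvs_per_genus = 25L,
                    samples_per_site = c(63L, 25L, 13L, 24L, 15L),
                    site_effect_size = 0.8,
                    fraction_low_depth = 4 / 140,
                    abundance_sd = 1.5,
                    evenness_scale = c(Site_1 = 1, Site_2 = 1, Site_3 = 1,
                                       Site_4 = 1.4, Site_5 = 1),
                    site_suppression = list(
                      Site_4 = list(fraction = 0.75, shift = 4)),
                    indicator_spec = indicators,
                    module_spec = modules,
                    module_boost = -2)
}

#' Write a simulated dataset to a directory
#'
#' Emits exactly the formats the readers consume: `counts.tsv`,
#' `taxonomy.tsv`, `metadata.tsv`, `tree.nwk`, plus `truth.json` and
#' `config.json`.
#'
#' @param dataset result of [simulate_communities()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$table, file.path(dir, "counts.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  truth$site_means <- NULL  # bulky; regenerate from config if needed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- dataset$config
  cfg$env_spec <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
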