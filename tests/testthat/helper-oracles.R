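# Independent oracles, deliberately written by a different route than the
# package implementations they check.

# feature table from a plain matrix with default ids
ft <- function(m, features = sprintf("f%02d", seq_len(nrow(m))),
               samples = sprintf("s%02d", seq_len(ncol(m))), ...) {
  dimnames(m) <- list(features, samples)
  feature_table(m, ...)
}

# UniFrac by per-edge recursive descendant enumeration
oracle_unifrac <- function(counts, tree, weighted, normalized = TRUE) {
  props <- sweep(counts, 2, colSums(counts), "/")
  ntip <- length(tree$tip.label)
  num <- 0; den_w <- 0; len_diff <- 0; len_union <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= ntip) child else
      unlist(phangorn::Descendants(tree, child, "tips"))
    labs <- intersect(tree$tip.label[tips], rownames(props))
    pa <- sum(props[labs, 1L]); pb <- sum(props[labs, 2L])
    l <- tree$edge.length[e]
    num <- num + l * abs(pa - pb)
    den_w <- den_w + l * (pa + pb)
    if (xor(pa > 0, pb > 0)) len_diff <- len_diff + l
    if (pa > 0 || pb > 0) len_union <- len_union + l
  }
  if (weighted) {
    if (normalized) { if (den_w == 0) 0 else num / den_w } else num
  } else {
    if (len_union == 0) 0 else len_diff / len_union
  }
}

# Faith's PD by per-edge descendant enumeration (rooted convention)
oracle_faith_pd <- function(present, tree) {
  ntip <- length(tree$tip.label)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= ntip) child else
      unlist(phangorn::Descendants(tree, child, "tips"))
    if (any(tree$tip.label[tips] %in% present)) {
      total <- total + tree$edge.length[e]
    }
  }
  total
}

# node metrics by hand-rolled BFS on an adjacency list
oracle_node_metrics <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
    adj[[edges$to[k]]] <- c(adj[[edges$to[k]]], edges$from[k])
  }
  dg <- lengths(adj)
  bfs <- function(start) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    dist
  }
  out <- data.frame(genus = nodes, DG = unname(dg), NC = NA_real_,
                    CC = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(nodes)) {
    nb <- adj[[nodes[i]]]
    out$NC[i] <- if (length(nb)) mean(dg[nb]) else NA_real_
    d <- bfs(nodes[i])[-i]
    reach <- is.finite(d)
    out$CC[i] <- if (any(reach)) 1 / mean(d[reach]) else 0
  }
  out
}

# random Erdos-Renyi-ish edge list over n named nodes
random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  list(nodes = nodes,
       edges = data.frame(from = pairs[1L, keep], to = pairs[2L, keep],
                          rho = stats::runif(sum(keep), 0.4, 0.9),
                          sign = "positive", p_adj = 0.01,
                          stringsAsFactors = FALSE))
}

# module-recovery study conditions: two 10-genus modules (3 negative
# loadings) planted at |rho| = 0.7 among 40 single-ASV genera, module taxa
# kept low-share (offset -2), 30 samples, depth ~50k
module_recovery_config <- function(seed, n_samples = 30L) {
  genera <- sprintf("Genus_%03d", 1:40)
  modules <- lapply(0:1, function(k) {
    list(genera = genera[11 + k * 10 + 0:9],
         loadings = c(1, 1, 1, 1, 1, 1, 1, -1, -1, -1),
         target_rho = 0.7, sites = NULL)
  })
  simulation_config(seed = seed, site_names = "Site_1",
                    samples_per_site = n_samples, n_taxa = 40L,
                    asvs_per_genus = 1L, site_effect_size = 0,
                    abundance_sd = 1, depth_meanlog = log(50000),
                    module_spec = modules, module_boost = -2)
}

edge_keys <- function(df) paste(pmin(df$from, df$to), pmax(df$from, df$to))
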