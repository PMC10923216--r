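#' Spearman correlation and p-value matrices for one site
#'
#' Spearman's rho between every pair of genera (rows) across the site's
#' samples, computed as Pearson correlation of average ranks; p-values from
#' the t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' (`exact_p = TRUE` switches to exact permutation enumeration, only
#' sensible for very small n). Constant genera are excluded with a warning
#' (their correlation is undefined).
#'
#' @param table `feature_table` for a single site, genera in rows; at least
#'   4 samples.
#' @param exact_p exact permutation p-values instead of the t approximation.
#' @return list with `rho` and `p` (square symmetric matrices over the
#'   retained genera) and `n` (sample count).
#' @export
spearman_matrix <- function(table, exact_p = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$counts
  if (ncol(m) < 4) stop("need at least 4 samples for correlation")
  if (nrow(m) < 2) stop("need at least 2 genera")
  keep <- apply(m, 1L, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning("excluding constant genus(era): ",
            paste(utils::head(rownames(m)[!keep], 5), collapse = ", "))
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 non-constant genera")
  }
  R <- t(apply(m, 1L, rank))               # average ranks for ties
  rho <- stats::cor(t(R))
  n <- ncol(m)
  if (exact_p) {
    p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
    perms <- permutations_of(n)
    for (i in seq_len(nrow(rho) - 1L)) {
      for (j in (i + 1L):nrow(rho)) {
        obs <- abs(rho[i, j])
        rs <- apply(perms, 1L, function(pm) stats::cor(R[i, ], R[j, pm]))
        p[i, j] <- p[j, i] <- mean(abs(rs) >= obs - 1e-12)
      }
    }
    diag(p) <- 0
  } else {
    r2 <- pmin(rho^2, 1 - 1e-15)
    tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    diag(p) <- 0
  }
  list(rho = rho, p = p, n = n)
}

permutations_of <- function(n) {
  if (n > 8) stop("exact permutation p only supported for n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Build a signed co-activity network from correlation matrices
#'
#' Benjamini-Hochberg FDR over all unique genus pairs with a defined rho;
#' an edge is kept iff `|rho| > threshold` and adjusted p `< alpha` (the
#' study defaults: 0.4 and 0.05). Isolated genera stay in the node set —
#' they still carry activity. BH is applied within this network only.
#'
#' @param correlations result of [spearman_matrix()].
#' @param threshold absolute-rho edge threshold.
#' @param alpha FDR level.
#' @param site site label carried on the network.
#' @param activity optional named vector of per-genus activity (e.g. summed
#'   relative activity) for node annotation.
#' @param phylum optional named vector mapping genus to phylum.
#' @return object of class `coactivity_network`: list with `site`, `nodes`
#'   (data.frame genus/activity/phylum), `edges` (data.frame from/to/rho/
#'   sign/p_adj).
#' @export
build_network <- function(correlations, threshold = 0.4, alpha = 0.05,
                          site = "site", activity = NULL, phylum = NULL) {
  rho <- correlations$rho
  p <- correlations$p
  genera <- rownames(rho)
  ut <- upper.tri(rho)
  idx <- which(ut & !is.na(rho), arr.ind = TRUE)
  p_adj <- stats::p.adjust(p[idx], method = "BH")
  keep <- abs(rho[idx]) > threshold & p_adj < alpha
  edges <- data.frame(
    from = genera[idx[keep, 1L]],
    to = genera[idx[keep, 2L]],
    rho = rho[idx][keep],
    sign = ifelse(rho[idx][keep] > 0, "positive", "negative"),
    p_adj = p_adj[keep],
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(
    genus = genera,
    activity = if (is.null(activity)) NA_real_ else
      unname(activity[genera]),
    phylum = if (is.null(phylum)) NA_character_ else
      unname(phylum[genera]),
    stringsAsFactors = FALSE
  )
  structure(list(site = site, nodes = nodes, edges = edges),
            class = "coactivity_network")
}

#' @export
print.coactivity_network <- function(x, ...) {
  cat(sprintf("<coactivity_network> site %s: %d nodes, %d edges (%d +, %d -)\n",
              x$site, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[c("from", "to", "rho", "sign", "p_adj")],
    directed = FALSE, vertices = network$nodes)
}

#' Node topology metrics: degree, neighborhood connectivity, closeness
#'
#' `DG` is the node's edge count; `NC` the mean degree of its neighbors
#' (`NA` for isolated nodes); `CC` the reciprocal of the mean shortest-path
#' length to the nodes reachable from it (within-component convention;
#' isolated nodes score 0). `cc_normalized = TRUE` multiplies CC by the
#' reachable fraction `(n_reachable)/(n-1)`.
#'
#' @param network a `coactivity_network`.
#' @param cc_normalized normalize closeness by reachable fraction.
#' @return data.frame with columns genus, DG, NC, CC.
#' @export
node_metrics <- function(network, cc_normalized = FALSE) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  dg <- igraph::degree(g)
  sp <- igraph::distances(g)
  nc <- cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- igraph::neighbors(g, i)
    nc[i] <- if (length(nb)) mean(dg[as.integer(nb)]) else NA_real_
    di <- sp[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) {
      cc[i] <- 0
    } else {
      cc[i] <- 1 / mean(di[reach])
      if (cc_normalized) cc[i] <- cc[i] * sum(reach) / (n - 1)
    }
  }
  data.frame(genus = igraph::V(g)$name, DG = unname(dg), NC = nc, CC = cc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare node topology metrics across site networks
#'
#' Pools node-level DG/NC/CC across sites and applies [group_compare()]
#' (Kruskal-Wallis + BH pairwise Wilcoxon) per metric — nodes are treated
#' as observations, as is conventional for cross-network topology
#' comparisons (a pseudo-replication caveat worth keeping in mind). Also
#' returns per-site summaries: node count, edge count, positive/negative
#' edge counts, and the node with most negative edges.
#'
#' @param networks named list of `coactivity_network` (names = sites).
#' @param metrics which metrics to test.
#' @return list with `tests` (per metric, `group_test` or NA if fewer than
#'   two usable sites), `node_metrics` (pooled data.frame with `site`),
#'   `summary` (per-site data.frame).
#' @export
compare_networks <- function(networks, metrics = c("DG", "NC", "CC")) {
  if (length(networks) < 2) stop("need at least 2 site networks")
  if (is.null(names(networks))) {
    names(networks) <- vapply(networks, function(x) x$site, character(1))
  }
  pooled <- do.call(rbind, lapply(names(networks), function(s) {
    cbind(site = s, node_metrics(networks[[s]]))
  }))
  tests <- lapply(stats::setNames(metrics, metrics), function(mt) {
    v <- pooled[[mt]]
    ok <- !is.na(v)
    usable <- names(which(table(pooled$site[ok]) >= 2))
    if (length(usable) < 2) {
      warning("fewer than 2 sites with 2+ values for ", mt)
      return(NULL)
    }
    sel <- ok & pooled$site %in% usable
    group_compare(v[sel], pooled$site[sel])
  })
  summary <- do.call(rbind, lapply(names(networks), function(s) {
    nw <- networks[[s]]
    neg <- nw$edges[nw$edges$sign == "negative", , drop = FALSE]
    neg_counts <- table(c(neg$from, neg$to))
    data.frame(
      site = s,
      n_nodes = nrow(nw$nodes),
      n_edges = nrow(nw$edges),
      n_positive = sum(nw$edges$sign == "positive"),
      n_negative = nrow(neg),
      most_negative_node = if (length(neg_counts))
        names(which.max(neg_counts)) else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  list(tests = tests, node_metrics = pooled, summary = summary)
}

#' Export a co-activity network
#'
#' `"edgelist"` writes a TSV (node1, node2, rho, sign, p_adj); `"graphml"`
#' writes GraphML with node attributes (activity, phylum, DG, NC, CC) via
#' \pkg{igraph}. `top_n` optionally restricts the export to the n most
#' active nodes (a visualization filter; metrics are always computed on the
#' full network).
#'
#' @param network a `coactivity_network`.
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @param top_n optional number of most-active nodes to keep.
#' @export
export_network <- function(network, path,
                           format = c("edgelist", "graphml"), top_n = NULL) {
  format <- match.arg(format)
  nw <- network
  if (!is.null(top_n) && top_n < nrow(nw$nodes)) {
    if (all(is.na(nw$nodes$activity))) {
      stop("top_n export needs node activities")
    }
    keep <- nw$nodes$genus[order(-nw$nodes$activity,
                                 nw$nodes$genus)][seq_len(top_n)]
    nw$nodes <- nw$nodes[nw$nodes$genus %in% keep, , drop = FALSE]
    nw$edges <- nw$edges[nw$edges$from %in% keep & nw$edges$to %in% keep, ,
                         drop = FALSE]
  }
  if (format == "edgelist") {
    out <- nw$edges
    names(out)[1:2] <- c("node1", "node2")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    mt <- node_metrics(nw)
    g <- as_igraph(nw)
    igraph::V(g)$DG <- mt$DG
    igraph::V(g)$NC <- mt$NC
    igraph::V(g)$CC <- mt$CC
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Per-site co-activity networks from a genus-level table
#'
#' Splits samples by site, computes Spearman matrices and builds one
#' network per site with [build_network()]. Sites with fewer than
#' `min_samples` samples are skipped with a warning.
#'
#' @param table genus-level `feature_table` (relative activity
#'   recommended).
#' @param metadata metadata with `sample_id` and `community`.
#' @param taxonomy optional taxonomy (for phylum annotation of genera).
#' @param threshold,alpha edge thresholds, see [build_network()].
#' @param min_samples minimum samples per site.
#' @return named list of `coactivity_network`.
#' @export
site_networks <- function(table, metadata, taxonomy = NULL,
                          threshold = 0.4, alpha = 0.05, min_samples = 4) {
  grp <- metadata$community[match(sample_ids(table), metadata$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata")
  phylum <- NULL
  if (!is.null(taxonomy)) {
    gmap <- unique(taxonomy[c("genus", "phylum")])
    gmap <- gmap[!duplicated(gmap$genus), ]
    phylum <- stats::setNames(gmap$phylum, gmap$genus)
  }
  out <- list()
  for (site in sort(unique(grp))) {
    ids <- sample_ids(table)[grp == site]
    if (length(ids) < min_samples) {
      warning(sprintf("site %s has %d < %d samples; skipped",
                      site, length(ids), min_samples))
      next
    }
    sub <- subset_table(table, samples = ids)
    sm <- withCallingHandlers(
      spearman_matrix(sub),
      warning = function(w) invokeRestart("muffleWarning"))
    act <- rowSums(sub$counts)
    out[[site]] <- build_network(sm, threshold = threshold, alpha = alpha,
                                 site = site, activity = act,
                                 phylum = phylum)
  }
  out
}
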