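test_that("Spearman matrix matches definitional rank computation", {
  m <- rbind(up = c(1, 2, 3, 4, 5, 6),
             down = c(6, 5, 4, 3, 2, 1),
             tied = c(2, 2, 3, 5, 4, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  sm <- spearman_matrix(feature_table(m))
  expect_equal(sm$rho["up", "down"], -1)
  expect_equal(sm$rho["up", "tied"],
               cor(rank(m["up", ]), rank(m["tied", ])), tolerance = 1e-12)
  # t-approximation p for the tied pair
  r <- sm$rho["up", "tied"]
  tstat <- abs(r) * sqrt(4 / (1 - r^2))
  expect_equal(sm$p["up", "tied"], 2 * pt(tstat, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  cst <- rbind(m, flat = rep(1, 6))
  expect_warning(sm2 <- spearman_matrix(feature_table(cst)), "constant")
  expect_false("flat" %in% rownames(sm2$rho))
  expect_error(spearman_matrix(ft(matrix(1:6, 2, 3))), "at least 4")
})

test_that("edges require both |rho| > threshold and adjusted p < alpha", {
  genera <- c("g1", "g2", "g3", "g4")
  rho <- diag(4) * 0 + diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.39    # below threshold
  rho[1, 3] <- rho[3, 1] <- 0.50    # in, if p_adj small
  rho[2, 3] <- rho[3, 2] <- -0.45   # large p: out
  rho[1, 4] <- rho[4, 1] <- -0.60   # negative edge in
  rho[2, 4] <- rho[4, 2] <- 0.05
  rho[3, 4] <- rho[4, 3] <- 0.10
  diag(rho) <- 1
  p <- matrix(0.9, 4, 4); diag(p) <- 0
  p[1, 3] <- p[3, 1] <- 1e-4
  p[2, 3] <- p[3, 2] <- 0.60
  p[1, 4] <- p[4, 1] <- 1e-4
  p[1, 2] <- p[2, 1] <- 1e-6
  dimnames(rho) <- dimnames(p) <- list(genera, genera)
  nw <- build_network(list(rho = rho, p = p, n = 20), site = "S")
  keys <- edge_keys(nw$edges)
  expect_setequal(keys, c("g1 g3", "g1 g4"))
  expect_identical(nw$edges$sign[order(nw$edges$from)],
                   c("positive", "negative")[order(c(1, 2))])
  expect_identical(nrow(nw$nodes), 4L)   # isolated nodes retained
})

test_that("node metrics match hand enumeration on star and path graphs", {
  star <- structure(list(
    site = "S",
    nodes = data.frame(genus = c("hub", "l1", "l2", "l3", "l4"),
                       activity = NA_real_, phylum = NA_character_),
    edges = data.frame(from = "hub", to = c("l1", "l2", "l3", "l4"),
                       rho = 0.5, sign = "positive", p_adj = 0.01)),
    class = "coactivity_network")
  mt <- node_metrics(star)
  expect_equal(mt$DG[mt$genus == "hub"], 4)
  expect_equal(mt$NC[mt$genus == "hub"], 1)
  expect_equal(mt$DG[mt$genus == "l1"], 1)
  expect_equal(mt$NC[mt$genus == "l1"], 4)

  path <- star
  path$nodes <- data.frame(genus = c("a", "b", "c", "iso"),
                           activity = NA_real_, phylum = NA_character_)
  path$edges <- data.frame(from = c("a", "b"), to = c("b", "c"),
                           rho = 0.5, sign = "positive", p_adj = 0.01)
  mt2 <- node_metrics(path)
  expect_equal(mt2$CC[mt2$genus == "b"], 1)
  expect_equal(mt2$CC[mt2$genus == "a"], 1 / 1.5)
  expect_equal(mt2$DG[mt2$genus == "iso"], 0)
  expect_equal(mt2$CC[mt2$genus == "iso"], 0)
  expect_true(is.na(mt2$NC[mt2$genus == "iso"]))
})

test_that("node metrics equal the BFS oracle on random graphs", {
  for (seed in 1:25) {
    rg <- random_graph(12, p_edge = 0.2, seed = seed)
    nw <- list(site = "S",
               nodes = data.frame(genus = rg$nodes, activity = NA_real_,
                                  phylum = NA_character_),
               edges = rg$edges)
    class(nw) <- "coactivity_network"
    got <- node_metrics(nw)
    want <- oracle_node_metrics(rg$nodes, rg$edges)
    expect_equal(got[order(got$genus), ], want[order(want$genus), ],
                 ignore_attr = TRUE)
  }
})

test_that("network construction is invariant to genus ordering", {
  set.seed(9)
  m <- matrix(rlnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("s%02d", 1:20)))
  m[2, ] <- m[1, ] * exp(rnorm(20, 0, 0.2))
  tab <- feature_table(m)
  nw1 <- build_network(spearman_matrix(tab), site = "S")
  perm <- sample(10)
  nw2 <- build_network(spearman_matrix(subset_table(tab,
    features = rownames(m)[perm])), site = "S")
  expect_setequal(edge_keys(nw1$edges), edge_keys(nw2$edges))
})

test_that("cross-site comparison: isomorphic networks give p = 1 and sign
           counts are conserved", {
  mk <- function(nodes) {
    nw <- list(site = "x",
               nodes = data.frame(genus = nodes, activity = 1,
                                  phylum = "P"),
               edges = data.frame(from = nodes[c(1, 2)],
                                  to = nodes[c(2, 3)],
                                  rho = c(0.6, -0.5),
                                  sign = c("positive", "negative"),
                                  p_adj = 0.01))
    class(nw) <- "coactivity_network"
    nw
  }
  nets <- list(A = mk(sprintf("a%d", 1:4)), B = mk(sprintf("b%d", 1:4)))
  cmp <- suppressWarnings(compare_networks(nets))
  for (t in cmp$tests) if (!is.null(t)) expect_equal(t$p_value, 1)
  expect_equal(cmp$summary$n_positive + cmp$summary$n_negative,
               cmp$summary$n_edges)
  expect_identical(cmp$summary$most_negative_node,
                   c("a2", "b2"))  # ties resolved to first seen
})

test_that("exports round-trip through edge list and GraphML", {
  rg <- random_graph(8, 0.3, seed = 3)
  nw <- list(site = "S",
             nodes = data.frame(genus = rg$nodes,
                                activity = seq_along(rg$nodes),
                                phylum = "P1"),
             edges = rg$edges)
  class(nw) <- "coactivity_network"

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(nw, tsv, format = "edgelist")
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_setequal(paste(back$node1, back$node2), paste(rg$edges$from,
                                                       rg$edges$to))
  expect_equal(sort(back$rho), sort(rg$edges$rho))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(nw, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 8)
  expect_equal(igraph::ecount(g), nrow(rg$edges))
  expect_true(all(c("activity", "phylum", "DG", "NC", "CC") %in%
                  igraph::vertex_attr_names(g)))

  # top-n export restricts to the most active nodes
  top <- withr::local_tempfile(fileext = ".tsv")
  export_network(nw, top, format = "edgelist", top_n = 3)
  kept <- utils::read.table(top, header = TRUE, sep = "\t")
  most_active <- rg$nodes[order(-seq_along(rg$nodes))][1:3]
  expect_true(all(c(kept$node1, kept$node2) %in% most_active))

  # empty network: header-only file, no error
  nw0 <- nw; nw0$edges <- nw$edges[0, ]
  e0 <- withr::local_tempfile(fileext = ".tsv")
  export_network(nw0, e0, format = "edgelist")
  expect_equal(nrow(utils::read.table(e0, header = TRUE, sep = "\t")), 0)
})
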