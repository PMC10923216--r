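#' Shannon entropy of a count or proportion vector
#'
#' `H = -sum p_i log p_i` over nonzero proportions, natural log (nats).
#'
#' @param counts nonnegative vector with positive total.
#' @return entropy in nats.
#' @export
shannon <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("zero total")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `J = H / log(S_obs)`; `NA` when a single taxon is observed (evenness
#' undefined).
#'
#' @inheritParams shannon
#' @return evenness in `[0, 1]`, or `NA`.
#' @export
pielou <- function(counts) {
  s <- sum(counts > 0)
  if (s < 2) return(NA_real_)
  shannon(counts) / log(s)
}

#' Chao1 richness estimate
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` by default,
#' where F1 and F2 are the singleton and doubleton counts; the classic
#' `S_obs + F1^2 / (2 F2)` is available via `bias_corrected = FALSE`
#' (infinite when F2 = 0 and F1 > 0). Requires integer counts — the
#' estimator is undefined on proportions.
#'
#' @param counts nonnegative integer vector.
#' @param bias_corrected logical.
#' @return richness estimate, `>= S_obs`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("Chao1 requires integer counts (undefined on proportions)")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f1 == 0) {
    s_obs
  } else {
    s_obs + f1^2 / (2 * f2)  # Inf when f2 == 0
  }
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal rooted subtree spanning the present
#' leaves and the root (the rooted convention: the root-to-subtree path
#' counts, so a single present leaf scores its full root-to-leaf path).
#'
#' @param present character vector of present feature identifiers (or a
#'   named count/presence vector: positives are present).
#' @param tree rooted `phylo` tree whose tips cover the features.
#' @return PD in branch-length units; 0 (with a warning) for an empty sample.
#' @export
faith_pd <- function(present, tree) {
  validate_tree(tree)
  if (is.numeric(present)) {
    if (is.null(names(present))) stop("numeric `present` must be named")
    present <- names(present)[present > 0]
  }
  if (!length(present)) {
    warning("empty sample: PD = 0")
    return(0)
  }
  missing_t <- setdiff(present, tree$tip.label)
  if (length(missing_t)) {
    stop("feature(s) absent from tree: ", paste(missing_t, collapse = ", "))
  }
  pres <- matrix(as.numeric(tree$tip.label %in% present),
                 nrow = length(tree$tip.label), ncol = 1,
                 dimnames = list(tree$tip.label, "s"))
  desc <- branch_sample_matrix(tree, pres)
  sum(tree$edge.length[desc[, 1L] > 0])
}

#' Per-sample alpha diversity table
#'
#' Shannon (nats), observed richness, Pielou evenness, singleton and
#' doubleton counts, Chao1, and (when a tree is supplied) Faith's PD for
#' every sample of a raw count table.
#'
#' @param table raw-count `feature_table`.
#' @param tree optional rooted `phylo` over the table's features.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (table$is_relative) {
    stop("alpha diversity (Chao1) needs raw integer counts")
  }
  m <- table$counts
  res <- data.frame(
    sample_id = colnames(m),
    H = apply(m, 2L, shannon),
    S_obs = colSums(m > 0),
    J = apply(m, 2L, pielou),
    F1 = colSums(m == 1),
    F2 = colSums(m == 2),
    chao1 = apply(m, 2L, chao1),
    row.names = NULL
  )
  if (!is.null(tree)) {
    missing_t <- setdiff(rownames(m), tree$tip.label)
    if (length(missing_t)) {
      stop("feature(s) absent from tree: ",
           paste(utils::head(missing_t, 5), collapse = ", "))
    }
    bsm <- branch_sample_matrix(tree, m)
    res$PD <- colSums(tree$edge.length * (bsm > 0))
  }
  res
}

#' Alpha diversity with per-index group tests
#'
#' Runs [alpha_diversity()] and then [group_compare()] (Kruskal-Wallis +
#' BH-adjusted pairwise Wilcoxon) for each index across the metadata's
#' `community` groups.
#'
#' @param table raw-count `feature_table`.
#' @param tree optional rooted `phylo`.
#' @param metadata metadata data.frame with `sample_id` and `community`.
#' @param indices which indices to test across groups.
#' @return list with `per_sample` (data.frame) and `tests` (named list of
#'   `group_test` objects).
#' @export
alpha_pipeline <- function(table, tree = NULL, metadata,
                           indices = c("J", "chao1", if (!is.null(tree)) "PD")) {
  res <- alpha_diversity(table, tree)
  grp <- metadata$community[match(res$sample_id, metadata$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata: ",
                       paste(res$sample_id[is.na(grp)], collapse = ", "))
  res$community <- grp
  tests <- lapply(stats::setNames(indices, indices), function(ix) {
    group_compare(res[[ix]], grp)
  })
  list(per_sample = res, tests = tests)
}

# Branch x sample matrix of descendant totals: entry (b, j) is the summed
# value (count, presence, proportion) over the leaves below edge b in
# sample j. One postorder pass; shared by UniFrac and Faith's PD.
branch_sample_matrix <- function(tree, m) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nnode, ncol(m))
  acc[seq_len(ntip), ] <- m[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    acc[parent, ] <- acc[parent, ] + acc[child, ]
  }
  # rows of the result follow tree$edge order (the original tree's edges)
  out <- acc[tree$edge[, 2L], , drop = FALSE]
  colnames(out) <- colnames(m)
  out
}
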