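#' UniFrac distances between all sample pairs
#'
#' Branch-wise phylogenetic dissimilarity over the rooted tree's edges.
#' With `p_X(b)` the fraction of sample X's total assigned to leaves below
#' branch b of length `l_b`:
#' \itemize{
#'   \item unweighted: `sum(l_b * [presence differs]) / sum(l_b)` over
#'     branches leading to taxa observed in at least one of the two samples;
#'   \item weighted raw: `sum(l_b * |p_A(b) - p_B(b)|)`;
#'   \item weighted normalized: the raw sum divided by
#'     `sum(l_b * (p_A(b) + p_B(b)))`.
#' }
#' Implemented with a single postorder accumulation of branch-wise
#' descendant totals, then pairwise combination.
#'
#' @param table a `feature_table` (raw or relative); every feature must be a
#'   tree tip, and every sample must have a positive total.
#' @param tree rooted `phylo` with branch lengths.
#' @param weighted logical.
#' @param normalized logical; ignored for unweighted (which is normalized by
#'   definition).
#' @return symmetric distance matrix over samples (zero diagonal).
#' @export
unifrac <- function(table, tree, weighted = TRUE, normalized = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  validate_tree(tree)
  m <- table$counts
  missing_t <- setdiff(rownames(m), tree$tip.label)
  if (length(missing_t)) {
    stop("feature(s) absent from tree: ",
         paste(utils::head(missing_t, 5), collapse = ", "))
  }
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("empty sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  }
  # pad to the full tip set so the accumulation covers every edge
  full <- matrix(0, length(tree$tip.label), ncol(m),
                 dimnames = list(tree$tip.label, colnames(m)))
  full[rownames(m), ] <- sweep(m, 2L, tot, "/")
  P <- branch_sample_matrix(tree, full)   # edges x samples proportions
  len <- tree$edge.length
  ns <- ncol(P)
  D <- matrix(0, ns, ns, dimnames = list(colnames(P), colnames(P)))
  pres <- P > 0
  for (a in seq_len(ns - 1L)) {
    for (b in (a + 1L):ns) {
      if (weighted) {
        num <- sum(len * abs(P[, a] - P[, b]))
        d <- if (normalized) {
          den <- sum(len * (P[, a] + P[, b]))
          if (den == 0) 0 else num / den
        } else num
      } else {
        union_b <- pres[, a] | pres[, b]
        den <- sum(len[union_b])
        d <- if (den == 0) 0 else
          sum(len[xor(pres[, a], pres[, b])]) / den
      }
      D[a, b] <- D[b, a] <- d
    }
  }
  D
}
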