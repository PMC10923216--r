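#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q-criterion, with branch lengths from the standard two-point
#' formulas. Negative estimated branch lengths are clamped to zero and the
#' deficit moved to the sister branch (so pairwise path lengths through the
#' join are preserved); set `clamp_negative = FALSE` to keep raw estimates.
#' The last three clusters are attached to a single top node with the
#' three-point formulas, which acts as the root; `rooting = "midpoint"`
#' re-roots at the midpoint of the longest leaf-to-leaf path instead
#' (binary root).
#'
#' On an additive (tree-realizable) distance matrix the result reproduces
#' every pairwise distance exactly.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 taxa,
#'   labelled.
#' @param clamp_negative clamp negative branch estimates to zero.
#' @param rooting `"last-join"` (default) or `"midpoint"`.
#' @return an `ape::phylo` tree whose tips are the matrix labels.
#' @export
nj_tree <- function(d, clamp_negative = TRUE,
                    rooting = c("last-join", "midpoint")) {
  rooting <- match.arg(rooting)
  m <- as.matrix(d)
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) stop("asymmetric distance matrix")
  labels <- rownames(m)

  # active clusters held as newick fragments (label:length already applied
  # at join time)
  frag <- labels
  n <- length(frag)
  dimnames(m) <- NULL

  clamp <- function(vi, vj) {
    if (clamp_negative) {
      if (vi < 0) { vj <- vj + vi; vi <- 0 }
      if (vj < 0) { vi <- vi + vj; vj <- 0 }
      vi <- max(vi, 0); vj <- max(vj, 0)
    }
    c(vi, vj)
  }

  while (n > 3) {
    r <- rowSums(m)
    q <- (n - 2) * m - outer(r, r, "+")
    diag(q) <- Inf
    k <- arrayInd(which.min(q), dim(q))
    i <- min(k); j <- max(k)
    vi <- 0.5 * m[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- m[i, j] - vi
    v <- clamp(vi, vj)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], v[1L], frag[j], v[2L])
    du <- 0.5 * (m[i, ] + m[j, ] - m[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    m <- m2
    n <- n - 1L
  }
  # three-point attachment at the top node
  v1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  v2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  v3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  if (clamp_negative) { v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0) }
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1L], v1, frag[2L], v2, frag[3L], v3)
  tree <- ape::read.tree(text = nwk)
  if (rooting == "midpoint") tree <- phangorn::midpoint(tree)
  tree
}
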