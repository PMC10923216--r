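#' IndVal components for one taxon and target group
#'
#' Specificity `A` = mean abundance of the taxon in the target group divided
#' by the sum of its per-group mean abundances (means, not sums, so the
#' statistic is corrected for unequal group sizes — essential with site
#' sample sizes ranging from 7 to 63). Sensitivity `B` = fraction of target
#' samples where the taxon occurs. `IndVal = sqrt(A * B)`.
#'
#' @param table a `feature_table` (relative activity recommended: `A` is
#'   then invariant to per-sample depth).
#' @param groups named group vector over the table's samples.
#' @param taxon feature identifier.
#' @param target group label, or vector of labels for a site combination.
#' @param size_corrected use group means (default); `FALSE` uses group sums
#'   (the classic uncorrected variant).
#' @return list with `A`, `B`, `indval`; `A` is `NA` (flagged) for a taxon
#'   absent everywhere.
#' @export
indval_components <- function(table, groups, taxon, target,
                              size_corrected = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (!taxon %in% feature_ids(table)) stop("unknown taxon: ", taxon)
  g <- align_groups(groups, sample_ids(table))
  if (!all(target %in% levels(g))) stop("unknown target group(s)")
  x <- table$counts[taxon, ]
  stat_fun <- if (size_corrected) mean else sum
  per_group <- tapply(x, g, stat_fun)
  in_target <- g %in% target
  A <- if (sum(per_group) == 0) NA_real_ else
    sum(per_group[target]) / sum(per_group)
  B <- mean(x[in_target] > 0)
  list(A = A, B = B,
       indval = if (is.na(A)) NA_real_ else sqrt(A * B))
}

#' Indicator-taxon analysis (IndVal) with a permutation null
#'
#' For every taxon, finds the group (or, with `allow_combinations = TRUE`,
#' the proper nonempty group combination) maximizing IndVal, and computes a
#' permutation p-value by reshuffling the sample-to-group assignment and
#' recomputing the maximized statistic (`(1 + count)/(1 + B)` estimator).
#' Ties in the best-group search break toward the smaller combination, then
#' lexicographically. The conventional significance filter (IndVal > 0.5
#' and p < 0.05) is reported as a flag, not applied destructively.
#'
#' @inheritParams indval_components
#' @param n_permutations label permutations.
#' @param seed integer seed.
#' @param allow_combinations also search proper combinations of groups.
#' @param indval_threshold,alpha thresholds for the `significant` flag.
#' @return data.frame with columns taxon, group, A, B, indval, p,
#'   significant — one row per taxon, sorted by decreasing IndVal.
#' @export
indval_analysis <- function(table, groups, n_permutations = 9999,
                            seed = NULL, allow_combinations = FALSE,
                            size_corrected = TRUE,
                            indval_threshold = 0.5, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_groups(groups, sample_ids(table))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("group with zero samples")
  if (any(table(g) == 1)) {
    warning("group(s) with a single sample: permutation null is degenerate")
  }
  X <- table$counts
  combos <- group_combinations(levels(g), allow_combinations)
  obs <- indval_max(X, g, combos, size_corrected)
  if (!is.null(seed)) set.seed(seed)
  count <- rep(0L, nrow(X))
  for (b in seq_len(n_permutations)) {
    gp <- g[sample.int(length(g))]
    perm <- indval_max(X, gp, combos, size_corrected)
    count <- count + as.integer(perm$indval >= obs$indval - 1e-12)
  }
  p <- (1 + count) / (1 + n_permutations)
  res <- data.frame(taxon = rownames(X),
                    group = obs$group, A = obs$A, B = obs$B,
                    indval = obs$indval, p = p, row.names = NULL)
  res$significant <- !is.na(res$indval) &
    res$indval > indval_threshold & res$p < alpha
  res[order(-res$indval), ]
}

# best group (or combination) per taxon; vectorized over taxa
indval_max <- function(X, g, combos, size_corrected) {
  lev <- levels(g)
  Z <- outer(g, lev, "==") * 1            # samples x groups
  colnames(Z) <- lev
  n_g <- colSums(Z)
  P0 <- (X > 0) %*% Z                     # taxa x groups presence counts
  stat <- if (size_corrected) sweep(X %*% Z, 2L, n_g, "/") else X %*% Z
  prev <- sweep(P0, 2L, n_g, "/")         # taxa x groups prevalence
  tot <- rowSums(stat)
  best_iv <- rep(-Inf, nrow(X))
  best_k <- rep(NA_integer_, nrow(X))
  best_A <- best_B <- rep(NA_real_, nrow(X))
  for (k in seq_along(combos)) {
    cl <- combos[[k]]
    A <- rowSums(stat[, cl, drop = FALSE]) / tot
    B <- if (length(cl) == 1L) prev[, cl] else
      rowSums(P0[, cl, drop = FALSE]) / sum(n_g[cl])
    iv <- sqrt(A * B)
    iv[tot == 0] <- NA
    better <- !is.na(iv) & iv > best_iv + 1e-12
    best_iv[better] <- iv[better]
    best_k[better] <- k
    best_A[better] <- A[better]
    best_B[better] <- B[better]
  }
  best_iv[!is.finite(best_iv)] <- NA
  list(indval = best_iv,
       group = vapply(best_k, function(k) {
         if (is.na(k)) NA_character_ else paste(combos[[k]], collapse = "+")
       }, character(1)),
       A = best_A, B = best_B)
}

# single groups first (smaller combinations win ties), lexicographic within
# a size; proper nonempty subsets only
group_combinations <- function(lev, allow_combinations) {
  lev <- sort(lev)
  if (!allow_combinations) return(as.list(lev))
  out <- list()
  for (size in seq_len(length(lev) - 1L)) {
    cc <- utils::combn(lev, size, simplify = FALSE)
    out <- c(out, cc)
  }
  out
}

align_groups <- function(groups, ids) {
  if (!is.null(names(groups))) {
    missing_s <- setdiff(ids, names(groups))
    if (length(missing_s)) stop("groups missing for sample(s): ",
                                paste(missing_s, collapse = ", "))
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("groups length must match sample count")
  }
  factor(as.character(groups))
}
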