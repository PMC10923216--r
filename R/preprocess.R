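#' Convert raw counts to relative activity
#'
#' Divides each sample column by its total so columns sum to one. With 16S
#' rRNA transcript data the proportions measure relative *activity* rather
#' than relative cell abundance.
#'
#' @param table a raw-count `feature_table`.
#' @return a `feature_table` with `is_relative = TRUE`.
#' @export
to_relative_activity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$is_relative) stop("table is already relative")
  tot <- colSums(table$counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total: ",
         paste(colnames(table$counts)[tot == 0], collapse = ", "))
  }
  feature_table(sweep(table$counts, 2L, tot, "/"), is_relative = TRUE)
}

#' Filter low-depth samples and rare features
#'
#' Samples whose total count falls below `min_sample_total` are removed
#' first; then features whose mean relative activity across the retained
#' samples falls below `min_mean_relative` are removed. The defaults are the
#' study thresholds (10,000 reads; 1e-5). `order = "features_first"`
#' computes feature means over all samples before dropping any.
#'
#' @param table raw-count `feature_table`.
#' @param min_sample_total minimum per-sample total count.
#' @param min_mean_relative minimum mean relative activity per feature.
#' @param order `"samples_first"` (default) or `"features_first"`.
#' @return list with `table` (filtered) and `report` listing
#'   `samples_removed` and `features_removed`.
#' @export
filter_dataset <- function(table, min_sample_total = 10000,
                           min_mean_relative = 1e-5,
                           order = c("samples_first", "features_first")) {
  stopifnot(inherits(table, "feature_table"), !table$is_relative)
  order <- match.arg(order)
  m <- table$counts

  drop_features <- function(m) {
    tot <- colSums(m)
    rel <- sweep(m, 2L, ifelse(tot == 0, 1, tot), "/")
    rowMeans(rel) < min_mean_relative
  }

  if (order == "features_first") {
    f_bad <- drop_features(m)
    if (all(f_bad)) stop("all features removed by the activity filter")
    m <- m[!f_bad, , drop = FALSE]
    s_bad <- colSums(m) < min_sample_total
    if (all(s_bad)) stop("all samples removed by the depth filter")
    m <- m[, !s_bad, drop = FALSE]
  } else {
    s_bad <- colSums(m) < min_sample_total
    if (all(s_bad)) stop("all samples removed by the depth filter")
    m <- m[, !s_bad, drop = FALSE]
    f_bad <- drop_features(m)
    if (all(f_bad)) stop("all features removed by the activity filter")
    m <- m[!f_bad, , drop = FALSE]
  }
  report <- list(
    samples_removed = setdiff(sample_ids(table), colnames(m)),
    features_removed = setdiff(feature_ids(table), rownames(m))
  )
  list(table = feature_table(m), report = report)
}

#' Aggregate features to a taxonomic rank
#'
#' Features sharing a name at `rank` are summed; features unresolved at that
#' rank are pooled into `"unassigned"`. Per-sample totals are conserved
#' exactly.
#'
#' @param table a `feature_table` (raw or relative).
#' @param taxonomy taxonomy data.frame ([read_taxonomy()]).
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return a `feature_table` whose feature identifiers are rank names.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank) {
  stopifnot(inherits(table, "feature_table"))
  if (!rank %in% TAXONOMIC_RANKS) {
    stop("unknown rank: ", rank, " (expected one of ",
         paste(TAXONOMIC_RANKS, collapse = ", "), ")")
  }
  lin <- taxonomy[[rank]][match(feature_ids(table), taxonomy$feature_id)]
  lin[is.na(lin)] <- UNASSIGNED
  agg <- rowsum(table$counts, group = lin)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  feature_table(agg, is_relative = table$is_relative)
}

#' Keep the n most active features
#'
#' Ranking is by mean relative activity across samples (computed on the fly
#' for raw tables). Ties at the cutoff are broken toward the
#' lexicographically smaller identifier so the selection is deterministic.
#'
#' @param table a `feature_table`.
#' @param n number of features to keep.
#' @return a `feature_table` with at most `n` features, most active first.
#' @export
top_n_features <- function(table, n = 50) {
  stopifnot(inherits(table, "feature_table"), n >= 1)
  m <- table$counts
  if (!table$is_relative) {
    tot <- colSums(m)
    m <- sweep(m, 2L, ifelse(tot == 0, 1, tot), "/")
  }
  score <- rowMeans(m)
  if (n > length(score)) {
    warning(sprintf("n = %d exceeds feature count %d; returning all",
                    n, length(score)))
    n <- length(score)
  }
  ord <- order(-score, rownames(table$counts))
  subset_table(table, features = rownames(table$counts)[ord[seq_len(n)]])
}

#' Prepare a clustered heatmap matrix
#'
#' The heatmap recipe: drop variables (features) with at least
#' `max_zero_fraction` zeros, drop variables whose interquartile range lies
#' below the `iqr_quantile` quantile of IQRs, Pareto-scale the survivors
#' (center, divide by the square root of the standard deviation), and
#' cluster rows and columns agglomeratively with distance = 1 - Pearson
#' correlation and Ward linkage.
#'
#' @param table a `feature_table` (variables are features).
#' @param max_zero_fraction variables with a zero fraction >= this are
#'   dropped.
#' @param iqr_filter logical, apply the IQR filter.
#' @param iqr_quantile quantile of IQRs below which variables are dropped.
#' @return list with `retained`, `scaled` (variables x samples, each
#'   variable row has mean 0), `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust`.
#' @export
heatmap_prep <- function(table, max_zero_fraction = 0.5, iqr_filter = TRUE,
                         iqr_quantile = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$counts
  zf <- rowMeans(m == 0)
  m <- m[zf < max_zero_fraction, , drop = FALSE]
  if (iqr_filter && nrow(m) > 1) {
    iqr <- apply(m, 1L, stats::IQR)
    m <- m[iqr >= stats::quantile(iqr, iqr_quantile), , drop = FALSE]
  }
  if (nrow(m) < 2) stop("fewer than 2 variables survive the heatmap filters")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  if (any(sdv == 0)) {
    m <- m[sdv > 0, , drop = FALSE]
    mu <- rowMeans(m); sdv <- apply(m, 1L, stats::sd)
    if (nrow(m) < 2) stop("fewer than 2 non-constant variables survive")
  }
  scaled <- (m - mu) / sqrt(sdv)
  pearson_dist <- function(x) stats::as.dist(1 - stats::cor(t(x)))
  rh <- stats::hclust(pearson_dist(scaled), method = "ward.D2")
  ch <- stats::hclust(pearson_dist(t(scaled)), method = "ward.D2")
  list(retained = rownames(scaled), scaled = scaled,
       row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch)
}

#' Pairwise Spearman screen of environmental variables
#'
#' Spearman's rho and p for every variable pair, dropping incomplete
#' samples pairwise, with a flag where |rho| exceeds `rho_threshold` and
#' p < `alpha` — the screen used to pick quasi-independent covariates
#' before ordination fitting.
#'
#' @param metadata metadata data.frame.
#' @param variables character vector of numeric metadata columns.
#' @param rho_threshold flag threshold on |rho|.
#' @param alpha flag threshold on p.
#' @return data.frame with columns var1, var2, n, rho, p, flagged.
#' @export
env_correlation_screen <- function(metadata, variables,
                                   rho_threshold = 0.21, alpha = 0.05) {
  missing_v <- setdiff(variables, names(metadata))
  if (length(missing_v)) stop("unknown variable(s): ",
                              paste(missing_v, collapse = ", "))
  pairs <- utils::combn(variables, 2L)
  out <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    n = NA_integer_, rho = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    x <- metadata[[pairs[1L, k]]]
    y <- metadata[[pairs[2L, k]]]
    ok <- stats::complete.cases(x, y)
    out$n[k] <- sum(ok)
    if (sum(ok) < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("constant variable in pair %s/%s; rho undefined",
                      pairs[1L, k], pairs[2L, k]))
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    out$rho[k] <- unname(ct$estimate)
    out$p[k] <- ct$p.value
  }
  out$flagged <- !is.na(out$rho) & abs(out$rho) > rho_threshold &
    out$p < alpha
  out
}

#' Fulton condition index
#'
#' `K = 100 * W / L^3` with weight in grams and fork length in centimeters;
#' K near 1 indicates a well-conditioned salmonid. The variant
#' `100 * (W/L)^3` that appears in some reports is available via
#' `as_printed = TRUE`; it is dimensionally inconsistent with the usual
#' healthy range (around 1.1) and is not the default.
#'
#' @param W weight (g), positive.
#' @param L fork length (cm), positive.
#' @param as_printed use the `100 * (W/L)^3` variant.
#' @return numeric vector of condition indices.
#' @export
fulton_index <- function(W, L, as_printed = FALSE) {
  if (any(!is.finite(W)) || any(!is.finite(L)) || any(W <= 0) || any(L <= 0)) {
    stop("W and L must be positive and finite")
  }
  if (as_printed) 100 * (W / L)^3 else 100 * W / L^3
}

#' Kruskal-Wallis group test with BH-adjusted pairwise Wilcoxon follow-up
#'
#' The package's standard nonparametric group comparison: overall
#' Kruskal-Wallis chi-squared (tie-corrected) and all pairwise two-sided
#' Wilcoxon rank-sum tests, Benjamini-Hochberg adjusted. Groups with fewer
#' than `min_group_size` observations are excluded with a warning.
#'
#' @param values numeric vector.
#' @param groups factor or character vector, same length.
#' @param min_group_size smallest usable group.
#' @return object of class `group_test`: list with `statistic` (chi-squared),
#'   `df`, `p_value`, `pairwise` (symmetric matrix of BH-adjusted p-values),
#'   `groups_used`.
#' @export
group_compare <- function(values, groups, min_group_size = 2) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    warning("excluding group(s) with fewer than ", min_group_size,
            " observations: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop("need at least 2 usable groups")
  kw <- stats::kruskal.test(values, factor(groups, levels = gl))
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, factor(groups, levels = gl),
                                p.adjust.method = "BH"))
  pmat <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  for (i in rownames(pw$p.value)) {
    for (j in colnames(pw$p.value)) {
      if (!is.na(pw$p.value[i, j])) {
        pmat[i, j] <- pmat[j, i] <- pw$p.value[i, j]
      }
    }
  }
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pmat, groups_used = gl),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("BH-adjusted pairwise Wilcoxon p-values:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}
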