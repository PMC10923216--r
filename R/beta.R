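#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' matrix `-0.5 * D^2`. Coordinates are returned for positive eigenvalues
#' (scaled by `sqrt(lambda)`); negative eigenvalues — which arise for
#' non-Euclidean dissimilarities such as weighted UniFrac — are reported and
#' their axes dropped, with proportion explained computed over the positive
#' part (`correction = "lingoes"` adds the Lingoes constant instead).
#'
#' @param d distance matrix or `dist`.
#' @param correction `"none"` (drop-and-report, default) or `"lingoes"`.
#' @return object of class `pcoa_result`: list with `coordinates` (samples x
#'   axes), `eigenvalues` (all, descending), `proportion_explained`,
#'   `negative_eigenvalues` and `correction`.
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples")
  B <- double_center(-0.5 * D^2)
  if (correction == "lingoes") {
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    c_l <- max(0, -min(ev))
    if (c_l > 0) {
      D2 <- D^2 + 2 * c_l
      diag(D2) <- 0
      B <- double_center(-0.5 * D2)
    }
  }
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                     length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    proportion_explained = ev[pos] / sum(ev[pos]),
    negative_eigenvalues = ev[ev < -tol],
    correction = correction
  ), class = "pcoa_result")
}

double_center <- function(A) {
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' PERMANOVA: permutation multivariate analysis of variance on a distance
#' matrix
#'
#' One-way partitioning of distance-based sums of squares:
#' `SS_T = sum(d_ij^2)/N` over all pairs, `SS_W = sum_g sum(d_ij^2)/n_g`
#' within groups, pseudo-F `= (SS_A/(a-1)) / (SS_W/(N-a))` with
#' `SS_A = SS_T - SS_W`. The p-value uses the `(1 + count)/(1 + B)`
#' estimator under whole-sample label permutation, so its floor is
#' `1/(B+1)` (1e-4 at 9,999 permutations). The permutation stream is drawn
#' after sorting samples by identifier, making the result independent of
#' input row order for a given seed.
#'
#' @param d distance matrix or `dist` with sample labels.
#' @param groups named vector (names = sample ids), or unnamed in matrix
#'   order; at least 2 groups with 2+ samples each.
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `df`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 9999, seed = NULL) {
  prep <- permanova_prep(d, groups)
  obs <- permanova_F(prep$D2, prep$g, prep$sizes)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    gp <- prep$g[sample.int(length(prep$g))]
    if (permanova_F(prep$D2, gp, prep$sizes)$F >= obs$F - 1e-12) {
      count <- count + 1L
    }
  }
  structure(list(
    pseudo_F = obs$F, R2 = obs$R2,
    p_value = (1 + count) / (1 + n_permutations),
    df = c(between = length(prep$sizes) - 1L,
           within = length(prep$g) - length(prep$sizes)),
    n_permutations = n_permutations, seed = seed
  ), class = "permanova_result")
}

permanova_prep <- function(d, groups) {
  D <- as.matrix(d)
  if (!is.null(names(groups))) {
    missing_s <- setdiff(rownames(D), names(groups))
    if (length(missing_s)) stop("groups missing for: ",
                                paste(missing_s, collapse = ", "))
    groups <- groups[rownames(D)]
  }
  if (length(groups) != nrow(D)) stop("groups length must match samples")
  # canonical sample order so the seeded permutation stream is invariant
  # to the input's row order
  ord <- order(rownames(D))
  D <- D[ord, ord]
  g <- factor(as.character(groups)[ord])
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("singleton group(s): ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  if (all(D == 0)) stop("degenerate distance matrix (all zeros)")
  list(D2 = D^2, g = g, sizes = sizes)
}

permanova_F <- function(D2, g, sizes) {
  N <- length(g)
  a <- length(sizes)
  ss_t <- sum(D2) / (2 * N)
  idx <- split(seq_len(N), g)
  ss_w <- 0
  for (ix in idx) ss_w <- ss_w + sum(D2[ix, ix]) / (2 * length(ix))
  ss_a <- ss_t - ss_w
  list(F = (ss_a / (a - 1)) / (ss_w / (N - a)), R2 = ss_a / ss_t)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with BH adjustment
#'
#' [permanova()] on every group pair's sub-matrix, with Benjamini-Hochberg
#' adjustment across all pairs.
#'
#' @inheritParams permanova
#' @return data.frame with columns group1, group2, pseudo_F, R2, p, p_adj.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 9999, seed = NULL) {
  D <- as.matrix(d)
  if (is.null(names(groups))) names(groups) <- rownames(D)
  gl <- sort(unique(as.character(groups)))
  pairs <- utils::combn(gl, 2L)
  res <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    pseudo_F = NA_real_, R2 = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    ids <- names(groups)[groups %in% pairs[, k]]
    sub <- permanova(D[ids, ids], groups[ids], n_permutations,
                     seed = if (is.null(seed)) NULL else seed + k)
    res$pseudo_F[k] <- sub$pseudo_F
    res$R2[k] <- sub$R2
    res$p[k] <- sub$p_value
  }
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Homogeneity of multivariate dispersion (betadisper)
#'
#' Embeds the distance matrix by PCoA keeping all axes, computes each
#' sample's distance to its group centroid in that space (squared real-axis
#' distance minus squared imaginary-axis distance, truncated at zero — the
#' standard reduction for negative eigenvalues), and tests group equality of
#' those distances with a one-way F whose null distribution comes from
#' permuting samples across groups.
#'
#' @inheritParams permanova
#' @return list with `distances` (named per-sample centroid distances),
#'   `F`, `p_value`, `n_permutations`, `seed`.
#' @export
betadisper_test <- function(d, groups, n_permutations = 9999, seed = NULL) {
  D <- as.matrix(d)
  if (!is.null(names(groups))) groups <- groups[rownames(D)]
  ord <- order(rownames(D))
  D <- D[ord, ord]
  g <- factor(as.character(groups)[ord])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  zd <- centroid_distances(D, g)
  f_obs <- anova_F(zd, g)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    if (anova_F(zd, g[sample.int(length(g))]) >= f_obs - 1e-12) {
      count <- count + 1L
    }
  }
  list(distances = stats::setNames(zd, rownames(D)), F = f_obs,
       p_value = (1 + count) / (1 + n_permutations),
       n_permutations = n_permutations, seed = seed)
}

centroid_distances <- function(D, g) {
  B <- double_center(-0.5 * D^2)
  eg <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  neg <- eg$values < -tol
  Xr <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  Xi <- eg$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eg$values[neg]), sum(neg))
  d2 <- numeric(length(g))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    cr <- colMeans(Xr[idx, , drop = FALSE])
    d2r <- rowSums(sweep(Xr[idx, , drop = FALSE], 2L, cr)^2)
    d2i <- 0
    if (ncol(Xi)) {
      ci <- colMeans(Xi[idx, , drop = FALSE])
      d2i <- rowSums(sweep(Xi[idx, , drop = FALSE], 2L, ci)^2)
    }
    d2[idx] <- pmax(d2r - d2i, 0)
  }
  sqrt(d2)
}

anova_F <- function(y, g) {
  gm <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  ss_b <- sum(n * (gm - mean(y))^2)
  ss_w <- sum((y - gm[g])^2)
  a <- nlevels(g)
  (ss_b / (a - 1)) / (ss_w / (length(y) - a))
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 minimization via \pkg{vegan}'s `metaMDS`/`monoMDS`
#' engine (monotone regression with ties pooled), best of `n_starts` random
#' initializations, solution centered and principal-axis rotated.
#'
#' @param d distance matrix or `dist`.
#' @param k number of axes.
#' @param n_starts random starts.
#' @param seed integer seed.
#' @return list with `coordinates`, `stress` (in `[0, 1]`), `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = NULL) {
  dd <- stats::as.dist(d)
  if (attr(dd, "Size") <= k + 1) stop("need more than k + 1 samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(dd, k = k, trymax = n_starts, autotransform = FALSE,
                        wascores = FALSE, trace = 0)
  if (!fit$converged) warning("NMDS did not converge; returning best start")
  list(coordinates = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged))
}

#' Fit environmental vectors onto an ordination
#'
#' For each variable: least-squares regression on the ordination axes,
#' `R2` = squared multiple correlation, direction = unit-normalized
#' coefficient vector, permutation p-value from permuting the variable
#' (`(1 + count)/(1 + B)` estimator), Bonferroni-adjusted across variables.
#' Samples with a missing value are dropped per variable (complete-case)
#' and the retained n reported.
#'
#' @param coordinates samples x axes matrix (row names = sample ids).
#' @param env data.frame of numeric variables (row names or `sample_id`
#'   column matching the coordinates).
#' @param n_permutations permutations per variable.
#' @param seed integer seed.
#' @return data.frame with one row per variable: n, R2, direction cosines
#'   (`axis1..k`), p, p_adj.
#' @export
envfit_vectors <- function(coordinates, env, n_permutations = 9999,
                           seed = NULL) {
  X <- as.matrix(coordinates)
  if (!is.null(env$sample_id)) {
    rownames(env) <- env$sample_id
    env$sample_id <- NULL
  }
  env <- env[rownames(X), , drop = FALSE]
  k <- ncol(X)
  vars <- names(env)
  out <- data.frame(variable = vars, n = NA_integer_, R2 = NA_real_,
                    p = NA_real_)
  dircos <- matrix(NA_real_, length(vars), k,
                   dimnames = list(vars, paste0("axis", seq_len(k))))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(vars)) {
    y <- env[[vars[i]]]
    ok <- !is.na(y) & stats::complete.cases(X)
    out$n[i] <- sum(ok)
    if (sum(ok) < k + 2) next
    yy <- y[ok]
    if (stats::sd(yy) == 0) {
      warning("constant variable: ", vars[i])
      next
    }
    Xc <- scale(X[ok, , drop = FALSE], center = TRUE, scale = FALSE)
    yc <- yy - mean(yy)
    fit <- stats::lm.fit(Xc, yc)
    r2 <- 1 - sum(fit$residuals^2) / sum(yc^2)
    beta <- fit$coefficients
    dircos[i, ] <- beta / sqrt(sum(beta^2))
    # vectorized permutation null: project permuted responses on the axes
    H <- Xc %*% chol2inv(chol(crossprod(Xc))) %*% t(Xc)
    count <- 0L
    for (b in seq_len(n_permutations)) {
      yp <- yc[sample.int(length(yc))]
      r2p <- sum((H %*% yp)^2) / sum(yp^2)
      if (r2p >= r2 - 1e-12) count <- count + 1L
    }
    out$R2[i] <- r2
    out$p[i] <- (1 + count) / (1 + n_permutations)
  }
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  cbind(out, dircos)
}
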