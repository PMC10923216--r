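test_that("PCoA reconstructs Euclidean geometries exactly", {
  # collinear points 0-1-3: one informative axis, distances recovered
  d <- as.matrix(dist(c(0, 1, 3)))
  dimnames(d) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  res <- pcoa(d)
  expect_equal(sum(res$eigenvalues > 1e-9), 1)
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)

  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  rownames(X) <- sprintf("s%02d", 1:10)
  d2 <- as.matrix(dist(X))
  res2 <- pcoa(d2)
  expect_equal(as.matrix(dist(res2$coordinates)), d2, tolerance = 1e-9)
  expect_length(res2$negative_eigenvalues, 0)
  expect_true(all(diff(res2$eigenvalues) <= 1e-9))   # descending
  expect_equal(sum(res2$proportion_explained), 1)

  # non-Euclidean input: negative eigenvalues reported, dropped by default
  dn <- matrix(1, 4, 4) - diag(4)
  dn[1, 2] <- dn[2, 1] <- 2.5
  dimnames(dn) <- list(letters[1:4], letters[1:4])
  res3 <- pcoa(dn)
  expect_gt(length(res3$negative_eigenvalues), 0)
  res4 <- pcoa(dn, correction = "lingoes")
  expect_length(res4$negative_eigenvalues, 0)
})

test_that("PERMANOVA pseudo-F and R2 agree exactly with vegan::adonis2", {
  set.seed(8)
  X <- matrix(rnorm(72), 24, 3)
  rownames(X) <- sprintf("s%02d", 1:24)
  d <- as.matrix(dist(X))
  g <- setNames(rep(c("a", "b", "c"), each = 8), rownames(X))
  mine <- permanova(d, g, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ grp,
                        data = data.frame(grp = g), permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-12)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-12)
  expect_identical(mine$df, c(between = 2L, within = 21L))
})

test_that("PERMANOVA permutation stream is invariant to input row order", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  rownames(X) <- sprintf("s%02d", 1:20)
  d <- as.matrix(dist(X))
  g <- setNames(rep(c("a", "b"), 10), rownames(X))
  p1 <- permanova(d, g, 199, seed = 7)$p_value
  shuf <- sample(rownames(d))
  p2 <- permanova(d[shuf, shuf], g, 199, seed = 7)$p_value
  expect_identical(p1, p2)
})

test_that("PERMANOVA degenerate and near-null cases behave", {
  # two groups with identical point configurations: F ~ 0, p ~ 1
  pts <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  X <- rbind(pts, pts) + 1e-9 * matrix(seq_len(12), 6, 2)
  rownames(X) <- sprintf("s%d", 1:6)
  d <- as.matrix(dist(X))
  g <- setNames(rep(c("a", "b"), each = 3), rownames(X))
  res <- permanova(d, g, 199, seed = 3)
  expect_lt(res$pseudo_F, 1e-3)
  expect_gt(res$p_value, 0.9)

  expect_error(permanova(matrix(0, 4, 4,
    dimnames = list(letters[1:4], letters[1:4])),
    setNames(rep(c("a", "b"), 2), letters[1:4]), 99), "degenerate")
  expect_error(permanova(d, setNames(c("a", rep("b", 5)), rownames(X)), 99),
               "singleton")
})

test_that("pairwise PERMANOVA adjusts with BH and respects identical
           groups", {
  set.seed(12)
  X <- matrix(rnorm(36), 18, 2)
  rownames(X) <- sprintf("s%02d", 1:18)
  d <- as.matrix(dist(X))
  g <- setNames(rep(c("a", "b", "c"), each = 6), rownames(X))
  res <- pairwise_permanova(d, g, 99, seed = 1)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adj >= res$p))
  # one clearly displaced group reaches the BH-adjusted floor
  X2 <- X; X2[13:18, ] <- X2[13:18, ] + 50
  d2 <- as.matrix(dist(X2))
  res2 <- pairwise_permanova(d2, g, 99, seed = 1)
  hit <- res2[res2$group1 == "c" | res2$group2 == "c", ]
  expect_true(all(hit$p == 1 / 100))
})

test_that("betadisper distances match the definitional oracle and vegan", {
  set.seed(21)
  X <- matrix(rnorm(48), 24, 2)
  rownames(X) <- sprintf("s%02d", 1:24)
  d <- as.matrix(dist(X))
  g <- setNames(rep(c("a", "b"), each = 12), rownames(X))
  res <- betadisper_test(d, g, 199, seed = 2)
  # Euclidean data: centroid distances computable directly from X
  direct <- numeric(24)
  for (lev in c("a", "b")) {
    idx <- which(g == lev)
    cen <- colMeans(X[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(X[idx, ], 2, cen)^2))
  }
  expect_equal(unname(res$distances[rownames(X)]), direct, tolerance = 1e-9)
  ref <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(res$distances[rownames(X)]),
               unname(ref$distances[rownames(X)]), tolerance = 1e-9)

  # congruent (translated) configurations: equal dispersion, F ~ 0
  pts <- matrix(rnorm(20), 10, 2)
  Xc <- rbind(pts, pts + 100)
  rownames(Xc) <- sprintf("s%02d", 1:20)
  dc <- as.matrix(dist(Xc))
  gc <- setNames(rep(c("a", "b"), each = 10), rownames(Xc))
  resc <- betadisper_test(dc, gc, 199, seed = 4)
  expect_lt(resc$F, 1e-6)
  expect_gt(resc$p_value, 0.9)

  # one group scaled x3 around its centroid: detected at the floor
  Xs <- rbind(pts, 3 * pts + 100)
  rownames(Xs) <- rownames(Xc)
  ress <- betadisper_test(as.matrix(dist(Xs)), gc, 199, seed = 5)
  expect_equal(ress$p_value, 1 / 200)
})

test_that("NMDS represents planar configurations near-perfectly", {
  set.seed(31)
  X <- matrix(rnorm(16), 8, 2)
  rownames(X) <- sprintf("s%d", 1:8)
  d <- as.matrix(dist(X))
  res <- suppressWarnings(nmds(d, k = 2, n_starts = 10, seed = 1))
  expect_lt(res$stress, 1e-4)
  rec <- as.matrix(dist(res$coordinates))
  expect_gt(cor(rec[upper.tri(rec)], d[upper.tri(d)]), 0.999)
})

test_that("envfit matches closed-form OLS R2 and vegan, with Bonferroni", {
  set.seed(41)
  X <- matrix(rnorm(60), 30, 2,
              dimnames = list(sprintf("s%02d", 1:30), NULL))
  env <- data.frame(ax = X[, 1],
                    v1 = rnorm(30), v2 = X %*% c(1, 2) + rnorm(30, 0, 0.5),
                    row.names = rownames(X))
  res <- envfit_vectors(X, env, n_permutations = 199, seed = 1)
  # variable equal to axis 1: R2 = 1, direction (1, 0)
  expect_equal(res$R2[res$variable == "ax"], 1, tolerance = 1e-10)
  expect_equal(abs(unlist(res[res$variable == "ax", c("axis1", "axis2")])),
               c(axis1 = 1, axis2 = 0), tolerance = 1e-6)
  # closed-form OLS R2
  for (v in c("v1", "v2")) {
    r2_lm <- summary(lm(env[[v]] ~ X))$r.squared
    expect_equal(res$R2[res$variable == v], r2_lm, tolerance = 1e-10)
  }
  ref <- vegan::envfit(X, env, permutations = 199)
  expect_equal(res$R2, unname(ref$vectors$r), tolerance = 1e-10)
  expect_equal(res$p_adj, pmin(res$p * 3, 1))

  env$k <- 1
  expect_warning(res2 <- envfit_vectors(X, env, 99, seed = 2), "constant")
  expect_true(is.na(res2$R2[res2$variable == "k"]))
})
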