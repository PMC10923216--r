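test_that("relative activity normalizes columns and rejects empty samples", {
  tab <- ft(matrix(c(2, 3, 5, 0, 0, 0), 3))
  expect_error(to_relative_activity(tab), "s02")
  tab2 <- ft(matrix(c(2, 3, 5), 3))
  rel <- to_relative_activity(tab2)
  expect_equal(unname(rel$counts[, 1]), c(0.2, 0.3, 0.5))
  expect_true(rel$is_relative)
  expect_error(to_relative_activity(rel), "already relative")
  single <- to_relative_activity(ft(matrix(7, 1, 1)))
  expect_equal(unname(single$counts[1, 1]), 1)
})

test_that("filtering removes exactly the low-depth samples and rare features,
           and is idempotent", {
  m <- rbind(
    hi = c(11990, 8995, 14997),
    lo = c(10, 5, 3),          # ~0.04% mean relative activity: retained
    rare = c(0, 0, 0)          # zero everywhere: below 1e-5
  )
  colnames(m) <- c("sA", "sB", "sC")
  tab <- feature_table(m)
  res <- filter_dataset(tab)
  expect_identical(res$report$samples_removed, "sB")   # total 9000 < 10000
  expect_identical(res$report$features_removed, "rare")
  again <- filter_dataset(res$table)
  expect_identical(again$table$counts, res$table$counts)
  expect_length(unlist(again$report), 0)

  # feature threshold is computed on retained samples (samples-first order)
  m2 <- rbind(big = c(2e5, 1e5), tiny = c(1, 1))
  colnames(m2) <- c("s1", "s2")
  res2 <- filter_dataset(feature_table(m2))
  expect_identical(res2$report$features_removed, "tiny")  # mean rel ~7.5e-6

  expect_error(filter_dataset(feature_table(
    matrix(5, 1, 1, dimnames = list("a", "s")))), "all samples")
})

test_that("rank aggregation sums lineages, pools unassigned, and conserves
           sample totals", {
  tab <- ft(matrix(c(1, 3, 7, 2, 4, 9), 3), features = c("a1", "a2", "a3"))
  tax <- data.frame(feature_id = c("a1", "a2", "a3"),
                    kingdom = "k", phylum = c("P1", "P1", "P2"),
                    class = "c", order = "o", family = "f",
                    genus = c("Pseudomonas", "Pseudomonas", "unassigned"),
                    species = "s")
  gen <- aggregate_by_rank(tab, tax, "genus")
  expect_equal(unname(gen$counts["Pseudomonas", ]), c(4, 6))
  expect_equal(unname(gen$counts["unassigned", ]), c(7, 9))
  expect_equal(colSums(gen$counts), colSums(tab$counts))
  for (rank in c("phylum", "family", "species")) {
    expect_equal(colSums(aggregate_by_rank(tab, tax, rank)$counts),
                 colSums(tab$counts))
  }
  expect_error(aggregate_by_rank(tab, tax, "clade"), "unknown rank")
})

test_that("top_n_features ranks by mean relative activity with deterministic
           ties", {
  m <- rbind(a = c(5, 5), b = c(3, 3), c = c(2, 2))
  colnames(m) <- c("s1", "s2")
  top <- top_n_features(feature_table(m), 2)
  expect_identical(feature_ids(top), c("a", "b"))
  # tie at the cutoff: lexicographically smaller id kept
  m2 <- rbind(z = c(3, 3), b = c(3, 3), a = c(4, 4))
  colnames(m2) <- c("s1", "s2")
  top2 <- top_n_features(feature_table(m2), 2)
  expect_identical(feature_ids(top2), c("a", "b"))
  expect_warning(all3 <- top_n_features(feature_table(m2), 5), "exceeds")
  expect_identical(dim(all3)[1], 3L)
})

test_that("heatmap preparation filters, Pareto-scales and clusters", {
  set.seed(42)
  base <- matrix(rlnorm(8 * 12), 8, 12,
                 dimnames = list(sprintf("v%d", 1:8), sprintf("s%d", 1:12)))
  base["v1", 1:7] <- 0                      # 58% zeros: dropped
  base["v3", ] <- base["v2", ]              # identical pair: merged first
  hp <- heatmap_prep(ft(base, features = rownames(base),
                        samples = colnames(base)), iqr_filter = FALSE)
  expect_false("v1" %in% hp$retained)
  expect_equal(unname(rowMeans(hp$scaled)), rep(0, nrow(hp$scaled)),
               tolerance = 1e-9)
  # Pareto scaling: variance-4 variable is divided by sqrt(2)
  x <- c(1, 3, 5, 7, 5, 3, 1, 7, 3, 5, 1, 7)
  m2 <- rbind(v = x, w = x + seq(0.1, 1.2, by = 0.1), u = rev(x))
  colnames(m2) <- sprintf("s%d", 1:12)
  hp2 <- heatmap_prep(feature_table(m2), iqr_filter = FALSE)
  expect_equal(hp2$scaled["v", ], (x - mean(x)) / sqrt(stats::sd(x)),
               ignore_attr = TRUE)
  # identical variables have Pearson distance 0 and merge at height 0 first
  merged_first <- hp$row_hclust$merge[1, ]
  expect_setequal(hp$retained[-merged_first], c("v2", "v3"))
  expect_equal(hp$row_hclust$height[1], 0, tolerance = 1e-9)
})

test_that("environmental Spearman screen matches the rank formula and flags
           |rho| > 0.21", {
  md <- data.frame(sample_id = sprintf("s%d", 1:5),
                   a = c(1, 2, 3, 4, 5),
                   b = c(5, 4, 3, 2, 1),
                   c = c(2.0, 3.5, 1.0, 5.5, 4.0))
  scr <- env_correlation_screen(md, c("a", "b", "c"))
  ab <- scr[scr$var1 == "a" & scr$var2 == "b", ]
  expect_equal(ab$rho, -1)
  expect_true(ab$flagged)
  ac <- scr[scr$var1 == "a" & scr$var2 == "c", ]
  expect_equal(ac$rho, cor(rank(md$a), rank(md$c)), tolerance = 1e-12)
  md$k <- 1
  expect_warning(scr2 <- env_correlation_screen(md, c("a", "k")), "constant")
  expect_true(is.na(scr2$rho[1]))
})

test_that("Fulton index uses 100*W/L^3 with the printed variant behind a
           flag", {
  expect_equal(fulton_index(44.7^3 / 100, 44.7), 1)
  expect_equal(fulton_index(1000, 44.7), 1.12, tolerance = 0.005)
  expect_error(fulton_index(1000, 0), "positive")
  expect_error(fulton_index(-1, 10), "positive")
  expect_equal(fulton_index(1000, 44.7, as_printed = TRUE),
               100 * (1000 / 44.7)^3)
})

test_that("group_compare: Kruskal-Wallis with BH pairwise Wilcoxon", {
  # identical group distributions: chi-squared 0, p = 1
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("x", "y"), each = 4)
  res <- group_compare(v, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)

  # fully separated groups of 5: exact two-sided rank-sum tail 2/choose(10,5)
  v2 <- c(1:5, 11:15)
  g2 <- rep(c("lo", "hi"), each = 5)
  res2 <- group_compare(v2, g2)
  expect_equal(res2$pairwise["lo", "hi"], 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_true(isSymmetric(res2$pairwise))

  # undersized groups are excluded with a warning
  expect_warning(res3 <- group_compare(c(v2, 99), c(g2, "solo")), "solo")
  expect_identical(res3$groups_used, c("hi", "lo"))
})
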