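test_that("PCA separates planted groups and respects the sign convention", {
  tab <- generate_composition_table(
    24, 10, list(k = 2, shift_log2 = 2, components_per_group = 3,
                 noise_sd = 0.05), seed = 11)
  labels <- attr(tab, "labels")
  pca <- pca_compositions(tab, aerobic = labels == 1)
  # groups separate along PC1 with no overlap of score signs
  expect_true(all(pca$scores[labels == 1, 1] < 0))
  expect_true(all(pca$scores[labels == 2, 1] > 0))
  expect_equal(sum(pca$explained_variance), 1)
  # growth correlation is reported when growth rates are supplied
  g <- stats::runif(24)
  p2 <- pca_compositions(tab, growth = g)
  expect_true(is.finite(p2$pc2_growth_correlation$spearman))
  expect_true(is.finite(p2$pc2_growth_correlation$pearson))
})

test_that("degenerate composition matrices are handled explicitly", {
  flat <- matrix(5, 6, 4, dimnames = list(paste0("c", 1:6), paste0("x", 1:4)))
  # covariance PCA reports zero variance for duplicated condition rows
  pc <- pca_compositions(flat, standardize = FALSE)
  expect_true(all(pc$explained_variance[-1] < 1e-12 |
                    is.nan(pc$explained_variance[-1])))
  expect_true(all(abs(pc$scores) < 1e-12))
  # z-scored PCA cannot standardize constants
  expect_error(pca_compositions(flat, standardize = TRUE), "degenerate")
  expect_error(pca_compositions(flat[1:2, ]), "at least 3 conditions")
})

test_that("outlier calling recovers a planted deviation and nothing else", {
  # one deviant cell among 27 otherwise identical conditions gives a
  # sample z-score of (n-1)/sqrt(n) ~ 5
  tab <- generate_composition_table(
    27, 6, list(k = 1, shift_log2 = 0, noise_sd = 0,
                outlier_cells = data.frame(condition = 4, component = 2,
                                           log2_shift = 3)), seed = 2)
  out <- find_outliers(tab, z_thresh = 3)
  expect_equal(nrow(out), 1)
  expect_equal(out$condition_id, "cond_4")
  expect_equal(out$component_id, "comp_2")
  expect_equal(out$z, 26 / sqrt(27), tolerance = 1e-10)
  expect_gt(out$log2fc_vs_mean, 0)
  # identical conditions: no outliers, zero-variance columns skipped
  flat <- generate_composition_table(10, 4, list(noise_sd = 0), seed = 3)
  expect_equal(nrow(find_outliers(flat)), 0)
  # a value equal to the column mean has log2 fold change zero
  m <- matrix(c(rep(1, 9), 2), 5, 2,
              dimnames = list(paste0("c", 1:5), c("a", "b")))
  o <- find_outliers(m, z_thresh = 0.1)
  expect_equal(o$log2fc_vs_mean[o$condition_id == "c1" &
                                  o$component_id == "b"],
               log2(1 / 1.2))
})

test_that("Ward clustering recovers planted structure after normalization", {
  tab <- generate_composition_table(
    24, 8, list(k = 2, shift_log2 = 2, components_per_group = 2,
                noise_sd = 0.02), seed = 21)
  labels <- attr(tab, "labels")
  cl <- cluster_conditions(tab, k = 2)
  expect_equal(ari(cl$labels[names(labels)], labels), 1)
  # max-normalization maps every surviving component's maximum to 1
  normed <- meallocate:::max_normalize(tab)
  expect_equal(unname(apply(normed, 2, max)), rep(1, ncol(normed)))
  # k = 1 puts everything in one cluster
  expect_equal(unique(cluster_conditions(tab, k = 1)$labels), 1L)
  expect_error(cluster_conditions(tab, k = 99), "exceeds")
  # outlier conditions are excluded before clustering
  cl2 <- cluster_conditions(tab, outliers = data.frame(
    condition_id = "cond_1", component_id = "comp_1", z = 9,
    log2fc_vs_mean = 1))
  expect_false("cond_1" %in% names(cl2$labels))
  expect_equal(cl2$excluded_outliers, "cond_1")
})

test_that("the gap statistic selects the planted cluster count", {
  tab <- generate_composition_table(
    18, 8, list(k = 3, shift_log2 = 3, components_per_group = 2,
                noise_sd = 0.05), seed = 31)
  cl <- cluster_conditions(tab, k = "auto", k_range = 2:6, B = 25,
                           seed = 99)
  expect_equal(cl$k, 3L)
  expect_equal(ari(cl$labels, attr(tab, "labels")[names(cl$labels)]), 1)
  expect_true(is.data.frame(cl$gap_curve))
})

test_that("cluster characterization retains exactly the shifted components", {
  tab <- generate_composition_table(
    24, 8, list(k = 2, shift_log2 = 1, components_per_group = 1,
                noise_sd = 0.05), seed = 41)
  labels <- attr(tab, "labels")
  ch <- characterize_clusters(tab, labels)
  kept1 <- ch$component_id[ch$cluster == 1 & ch$retained]
  expect_setequal(kept1, c("comp_1", "comp_2"))
  lfc <- ch$log2fc[ch$cluster == 1 & ch$component_id == "comp_1"]
  expect_equal(lfc, 1, tolerance = 0.15)
  # swapping the two labels negates every fold change
  sw <- characterize_clusters(tab, 3 - labels)
  merged <- merge(ch, sw, by = c("cluster", "component_id"))
  expect_equal(merged$log2fc.x, -merged$log2fc.y, tolerance = 1e-10)
  # a constant component is never retained
  tab2 <- tab
  tab2[, 8] <- 1
  ch2 <- characterize_clusters(tab2, labels)
  expect_false(any(ch2$retained[ch2$component_id == "comp_8"]))
  # singleton clusters are skipped with a warning
  lab3 <- labels
  lab3[1] <- 3L
  expect_warning(characterize_clusters(tab, lab3), "single member")
})

test_that("conditional essentiality marks positive clamped demands", {
  m <- matrix(c(0, 1e-15, 0.2, 0.4), 2, 2,
              dimnames = list(c("c1", "c2"), c("q8", "nad")))
  attr(m, "component_class") <- c(q8 = "coenzyme", nad = "coenzyme")
  ess <- conditional_essentiality(m)
  expect_identical(ess[, "q8"], c(c1 = FALSE, c2 = FALSE))
  expect_identical(ess[, "nad"], c(c1 = TRUE, c2 = TRUE))
})

test_that("rank-sum p-values agree with exact permutation enumeration", {
  set.seed(17)
  sizes <- list(c(3, 5), c(4, 4), c(6, 8), c(8, 8), c(2, 7))
  for (sz in sizes) {
    x <- stats::rnorm(sz[1])
    y <- stats::rnorm(sz[2], mean = 0.8)
    p_impl <- stats::wilcox.test(x, y, alternative = "two.sided",
                                 exact = TRUE)$p.value
    expect_equal(p_impl, perm_wilcox_p(x, y), tolerance = 1e-12)
  }
})
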