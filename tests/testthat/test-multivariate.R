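# Distance matrices, PERMANOVA and the dispersion-homogeneity test.

test_that("Bray-Curtis distances match hand arithmetic", {
  x <- rbind(c(1, 0), c(0, 1), c(2, 1), c(1, 1))
  d <- bray_curtis_matrix(x)
  expect_equal(d[1, 2], 1)
  expect_equal(d[3, 4], 0.2)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(bray_curtis_matrix(rbind(c(2, 1), c(2, 1)))[1, 2], 0)
  expect_error(bray_curtis_matrix(rbind(c(1, 1), c(0, 0))), "exclude")
})

test_that("univariate Euclidean pseudo-F equals the classical ANOVA F", {
  set.seed(12)
  y <- rnorm(24)
  g <- factor(rep(letters[1:4], 6))
  pm <- permanova(as.matrix(dist(y)), ~ g, data.frame(g = g), n_perm = 19,
                  seed = 1)
  expect_equal(pm$aov_tab$pseudo_F[1], summary(stats::aov(y ~ g))[[1]]$F[1],
               tolerance = 1e-10)
  expect_equal(pm$aov_tab$df[1:2], c(3L, 20L))
})

test_that("small-sample permutation p is exact against enumeration", {
  set.seed(8)
  X <- matrix(rpois(6 * 4, 6), 6, 4)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  D <- bray_curtis_matrix(X)
  # independent oracle: classical distance-based one-way pseudo-F from
  # within-group interpoint distances, over all 720 relabellings
  oracle_f <- function(perm) {
    gg <- g[perm]
    n <- length(gg)
    sst <- sum(D[upper.tri(D)]^2) / n
    ssw <- 0
    for (lv in levels(gg)) {
      i <- which(gg == lv)
      sub <- D[i, i]
      ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(i)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  perms <- pelletdiet:::all_permutations(6)
  f_all <- vapply(perms, oracle_f, numeric(1))
  f_obs <- oracle_f(1:6)
  p_exact <- mean(f_all >= f_obs - 1e-12)
  pm <- permanova(D, ~ g, data.frame(g = g), n_perm = 720, seed = 2)
  expect_true(pm$exhaustive)
  expect_equal(pm$aov_tab$pseudo_F[1], f_obs, tolerance = 1e-10)
  expect_equal(pm$aov_tab$p_perm[1], p_exact, tolerance = 1e-12)
})

test_that("sequential SS partition matches vegan adonis2 on crossed designs", {
  set.seed(3)
  X <- matrix(rpois(40 * 6, 5), 40, 6)
  info <- data.frame(year = factor(rep(2009:2010, 20)),
                     area = factor(rep(c("H", "L", "N", "W"), each = 10)))
  d <- vegan::vegdist(X, "bray")
  pm <- permanova(as.matrix(d), ~ year * area, info, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(d ~ year * area, data = info, permutations = 99,
                       by = "terms")
  expect_equal(pm$aov_tab$ss, c(ad$SumOfSqs)[1:4], tolerance = 1e-10)
  expect_equal(pm$aov_tab$pseudo_F[1:3], c(ad$F)[1:3], tolerance = 1e-10)
  expect_equal(pm$aov_tab$df, c(ad$Df)[1:4])
  expect_equal(sum(pm$aov_tab$ss), pm$total_ss, tolerance = 1e-9)
  expect_equal(sum(pm$aov_tab$df), nrow(info) - 1L)
})

test_that("permanova SS are seed-invariant and relabelling-covariant", {
  set.seed(9)
  X <- matrix(rpois(30 * 5, 4) , 30, 5)
  X[rowSums(X) == 0, 1] <- 1
  info <- data.frame(g = factor(rep(1:3, 10)))
  D <- bray_curtis_matrix(X)
  a <- permanova(D, ~ g, info, n_perm = 49, seed = 1)
  b <- permanova(D, ~ g, info, n_perm = 49, seed = 999)
  expect_equal(a$aov_tab$ss, b$aov_tab$ss, tolerance = 1e-12)
  # reordering observations together with the design changes nothing
  ord <- sample(30)
  c2 <- permanova(D[ord, ord], ~ g, info[ord, , drop = FALSE], n_perm = 49,
                  seed = 1)
  expect_equal(c2$aov_tab$ss, a$aov_tab$ss, tolerance = 1e-10)
  expect_equal(c2$aov_tab$pseudo_F[1], a$aov_tab$pseudo_F[1],
               tolerance = 1e-10)
})

test_that("degenerate designs and data are rejected with clear errors", {
  D <- matrix(0, 4, 4)
  info <- data.frame(g = factor(c("a", "a", "b", "b")))
  expect_error(permanova(D, ~ g, info, n_perm = 9), "identical")
  X <- matrix(rpois(12, 5), 4, 3)
  D2 <- bray_curtis_matrix(X + 1)
  info$h <- info$g  # aliased copy of the same factor
  expect_error(permanova(D2, ~ g + h, info, n_perm = 9), "aliased.*h")
})

test_that("dispersion distances and F match the Levene-type construction", {
  # 1-D points: group A = {0, 2}, group B = {0, 4}
  y <- c(0, 2, 0, 4)
  g <- factor(c("A", "A", "B", "B"))
  dt <- dispersion_test(as.matrix(dist(y)), g, n_perm = 23, seed = 1)
  expect_equal(dt$distances, c(1, 1, 2, 2), tolerance = 1e-10)
  expect_equal(dt$group_stats$mean_dist, c(1, 2), tolerance = 1e-10)

  # coincident points in one group: its distances are all zero
  y2 <- c(1, 1, 1, 0, 3, 9)
  g2 <- factor(c("A", "A", "A", "B", "B", "B"))
  dt2 <- dispersion_test(as.matrix(dist(y2)), g2, n_perm = 23, seed = 1)
  expect_equal(dt2$distances[1:3], rep(0, 3), tolerance = 1e-10)
  # F from a hand one-way ANOVA on the centroid distances
  z <- dt2$distances
  expect_equal(dt2$F, summary(stats::aov(z ~ g2))[[1]]$F[1], tolerance = 1e-9)

  expect_error(dispersion_test(as.matrix(dist(y)), factor(c("A", "A", "A", "B")),
                               n_perm = 9), "size 1")
})

test_that("dispersion test agrees with vegan betadisper (centroid type)", {
  set.seed(4)
  X <- matrix(rpois(36 * 7, 5), 36, 7)
  X[rowSums(X) == 0, 1] <- 1
  g <- factor(rep(c("a", "b", "c"), each = 12))
  d <- vegan::vegdist(X, "bray")
  dt <- dispersion_test(as.matrix(d), g, n_perm = 49, seed = 2)
  bd <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(dt$distances, unname(bd$distances), tolerance = 1e-10)
  expect_equal(dt$F, stats::anova(bd)$F[1], tolerance = 1e-10)
})

test_that("mirror-image groups with equal spread give well-spread p-values", {
  set.seed(17)
  ps <- replicate(60, {
    base <- matrix(rnorm(10 * 3), 10, 3)
    X <- rbind(base, base * matrix(sample(c(-1, 1), 30, TRUE), 10, 3))
    g <- factor(rep(c("a", "b"), each = 10))
    dispersion_test(as.matrix(dist(X)), g, n_perm = 99)$p_perm
  })
  # null p-values should not pile up near 0: no more than ~1/10 below 0.05
  expect_lt(mean(ps <= 0.05), 0.15)
  expect_gt(mean(ps > 0.5), 0.25)
})
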