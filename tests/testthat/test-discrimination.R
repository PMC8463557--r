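test_that("distance matrices satisfy their definitions and metric properties", {
  m <- fake_matrix(rbind(c(0, 0), c(3, 4), c(0, 0)))
  d <- euclidean_distances(m)
  expect_equal(unname(d[1, 2]), 5)
  expect_equal(unname(d[1, 3]), 0)
  expect_equal(d, t(d))
  set.seed(2)
  r <- fake_matrix(matrix(runif(50), 10))
  dr <- euclidean_distances(r)
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(dr[i, j], dr[i, k] + dr[k, j] + 1e-12)
})

test_that("Bray-Curtis follows the sum formula", {
  m <- fake_matrix(rbind(c(1, 2, 3), c(2, 0, 3), c(1, 2, 3), c(0, 4, 0)))
  d <- bray_curtis(m)
  expect_equal(unname(d[1, 2]), 3 / 11, tolerance = 1e-12)
  expect_equal(unname(d[1, 3]), 0)
  disjoint <- fake_matrix(rbind(c(1, 0), c(0, 2)))
  expect_equal(unname(bray_curtis(disjoint)[1, 2]), 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(fake_matrix(rbind(c(0, 0), c(1, 1)))), "all-zero")
})

test_that("Ward clustering reproduces hand cases and singleton heights", {
  two <- fake_matrix(rbind(c(0, 0), c(3, 0)))
  dend <- ward_cluster(euclidean_distances(two))
  expect_equal(dend$hc$height, 3)   # singleton merge height equals d
  pts <- fake_matrix(cbind(c(0, 1, 10, 11), 0))
  dd <- ward_cluster(euclidean_distances(pts))
  expect_equal(dd$edges[[1]], c(1, 2))
  expect_equal(dd$edges[[2]], c(3, 4))
  expect_equal(dd$edges[[3]], 1:4)
  dup <- fake_matrix(rbind(c(1, 1), c(1, 1), c(5, 5)))
  expect_equal(ward_cluster(euclidean_distances(dup))$hc$height[1], 0)
})

test_that("Ward merges equal the brute-force minimal-variance-increase oracle", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(6:8, 1)
    X <- matrix(rnorm(n * 3), n)
    dend <- ward_cluster(dist(X))
    expect_identical(dend$edges, oracle_ward_merges(X))
  }
})

test_that("AU fit behaves at its analytic anchor points", {
  scales <- seq(0.5, 1.4, by = 0.1)
  B <- 1000L
  # BP = 0.5 at every scale -> v = c = 0 -> AU = 50
  half <- spectrotype:::fit_au(rep(500L, length(scales)), scales, B)
  expect_equal(half$au, 50, tolerance = 1e-9)
  expect_equal(half$bp, 50)
  # edge never recovered -> AU = 0 with the degenerate flag
  none <- spectrotype:::fit_au(rep(0L, length(scales)), scales, B)
  expect_true(none$degenerate)
  expect_equal(none$au, 0)
  # always recovered -> AU near 100, BP = 100 at r = 1
  full <- spectrotype:::fit_au(rep(B, length(scales)), scales, B)
  expect_gt(full$au, 99)
  expect_equal(full$bp, 100)
})

test_that("multiscale bootstrap gives full support to the root and separates clusters", {
  set.seed(4)
  m <- fake_matrix(rbind(matrix(rnorm(40, 0), 4),
                         matrix(rnorm(40, 12), 4)),
                   labels = rep(c("A", "B"), each = 4))
  dend <- au_bp(m, mb_params(replicates = 200, seed = 9))
  root <- length(dend$edges)
  expect_equal(dend$bp[root], 100)
  expect_equal(dend$au[root], 100, tolerance = 1e-6)
  # the two cluster edges are recovered essentially always
  sig <- vapply(dend$edges, paste, "", collapse = "-")
  eA <- match(paste(1:4, collapse = "-"), sig)
  eB <- match(paste(5:8, collapse = "-"), sig)
  expect_false(anyNA(c(eA, eB)))
  expect_gt(dend$bp[eA], 95)
  expect_gt(dend$au[eA], 95)
  expect_gt(dend$au[eB], 95)
  # BP at r = 1 is the raw proportion at that scale
  r1 <- which.min(abs(dend$params$scales - 1))
  expect_equal(dend$bp, 100 * dend$bp_counts[, r1] / 200)
  # reproducible bit-for-bit under the seed
  dend2 <- au_bp(m, mb_params(replicates = 200, seed = 9))
  expect_identical(dend$bp_counts, dend2$bp_counts)
})

test_that("DDA t-scores follow the stated formula", {
  # two groups 2/2, one feature separating them with zero within-group sd
  vals <- rbind(c(2, 5, 1), c(2, 6, 2), c(0, 5, 3), c(0, 6, 4))
  m <- fake_matrix(vals, labels = c("A", "A", "B", "B"))
  rk <- dda_rank(m)
  expect_equal(unname(rk$scores["A", 1]), -unname(rk$scores["B", 1]))
  expect_gt(rk$scores["A", 1], 0)
  # hand evaluation: xbar_A1 = 2, grand = 1, m_g = sqrt(1/2 - 1/4), s_1 = 0
  mg <- sqrt(1 / 2 - 1 / 4)
  s_j <- sqrt(c(0, sum(c(-0.5, 0.5, -0.5, 0.5)^2) / 2, sum(c(-0.5, 0.5, -0.5, 0.5)^2) / 2))
  s0 <- median(s_j)
  expect_equal(unname(rk$scores["A", 1]), (2 - 1) / (mg * (0 + s0)))
  # identical group means give zero score and lowest rank
  same <- fake_matrix(rbind(c(1, 9), c(3, 1), c(1, 5), c(3, 2)),
                      labels = c("A", "A", "B", "B"))
  rs <- dda_rank(same)
  expect_equal(unname(rs$scores[, 1]), c(0, 0))
  expect_equal(rs$order[length(rs$order)], 1L)
  # permuting feature order permutes scores without changing content
  perm <- c(3, 1, 2)
  rp <- dda_rank(fake_matrix(vals[, perm], labels = c("A", "A", "B", "B")))
  expect_equal(unname(rp$rank_stat), unname(rk$rank_stat[perm]))
  expect_error(dda_rank(fake_matrix(vals, labels = rep("A", 4))), "2 groups")
})

test_that("NMDS reaches zero stress on embeddable configurations", {
  set.seed(31)
  X <- matrix(runif(20), 10, 2)
  d <- as.matrix(dist(X))
  res <- nmds(d, k = 2, n_restarts = 4, seed = 1)
  expect_lt(res$stress, 1e-3)
  # any 3-point dissimilarity embeds in the plane
  for (rep in 1:5) {
    d3 <- matrix(0, 3, 3)
    d3[lower.tri(d3)] <- runif(3, 0.5, 2)
    d3 <- d3 + t(d3)
    expect_lt(nmds(d3, k = 2, n_restarts = 3, seed = rep)$stress, 1e-6)
  }
})

test_that("NMDS stress traces never increase and runs are seed-reproducible", {
  set.seed(12)
  m <- fake_matrix(matrix(rexp(60), 12), labels = rep(c("A", "B"), 6))
  d <- bray_curtis(m)
  res <- nmds(d, k = 2, n_restarts = 5, seed = 3)
  for (tr in res$all_traces) expect_true(all(diff(tr) <= 1e-12))
  res2 <- nmds(d, k = 2, n_restarts = 5, seed = 3)
  expect_identical(res$points, res2$points)
  # sanity against the reference implementation (same data, similar stress)
  ref <- vegan::monoMDS(as.dist(d), k = 2, model = "global")
  expect_lt(res$stress, ref$stress + 0.02)
})

test_that("dispersion test: mirror-image groups give F = 0, p = 1", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5, 5, 6), ncol = 2, byrow = TRUE)
  d <- as.matrix(dist(X))
  res <- dispersion_homogeneity(d, rep(c("A", "B"), each = 3))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_error(dispersion_homogeneity(d, c("A", rep("B", 5))), "2 members")
})

test_that("dispersion test agrees with the reference PCoA embedding", {
  set.seed(14)
  m <- fake_matrix(matrix(rexp(80), 16), labels = rep(c("A", "B"), each = 8))
  d <- bray_curtis(m)
  mine <- dispersion_homogeneity(d, attr(m, "species"))
  bd <- vegan::betadisper(as.dist(d), attr(m, "species"), type = "centroid")
  ref <- anova(bd)
  expect_equal(unname(sort(mine$distances)), unname(sort(bd$distances)),
               tolerance = 1e-8)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("PERMANOVA matches the reference pseudo-F and its exhaustive minimum", {
  set.seed(15)
  m <- fake_matrix(matrix(rexp(60), 12), labels = rep(c("A", "B", "C"), 4))
  labels <- attr(m, "species")
  d <- bray_curtis(m)
  mine <- permanova(d, labels, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = labels),
                        permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-8)
  # strongly separated clusters: no relabeling can beat the observed F,
  # verified exhaustively at n = 4 + 4
  X <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 20, 0.1), 4))
  dX <- as.matrix(dist(X))
  lab <- rep(c("A", "B"), each = 4)
  f_obs <- permanova(dX, lab, n_perm = 1, seed = 1)$statistic
  combs <- combn(8, 4)
  f_all <- apply(combs, 2, function(idx) {
    lp <- rep("B", 8); lp[idx] <- "A"
    permanova(dX, lp, n_perm = 1, seed = 1)$statistic
  })
  expect_equal(max(f_all), f_obs, tolerance = 1e-10)
  expect_equal(sum(f_all >= f_obs - 1e-10), 2L)  # only the true split and its mirror
  # pseudo-F invariant under permutation of sample order
  p <- sample(8)
  expect_equal(permanova(dX[p, p], lab[p], n_perm = 1, seed = 1)$statistic,
               f_obs, tolerance = 1e-10)
  expect_error(permanova(dX, rep("A", 8), n_perm = 9), "2 groups")
})
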