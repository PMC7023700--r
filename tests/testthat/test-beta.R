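test_that("Bray-Curtis follows the defining formula", {
  tab <- toy_table(cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["a", "b"], 0.5)      # (1+0+1)/(1+2+1)
  expect_equal(d["a", "c"], 0)
  disj <- toy_table(cbind(a = c(2, 0), b = c(0, 3)))
  expect_equal(as.matrix(bray_curtis(disj))["a", "b"], 1)
  zz <- toy_table(cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1)))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("binary Bray-Curtis equals the Sorensen identity on random tables", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rbinom(40, 1, 0.5) * rpois(40, 4), 8, 5)
    m[, colSums(m) == 0] <- 1  # avoid empty samples
    d <- as.matrix(bray_curtis(toy_table(m), binary = TRUE))
    pres <- m > 0
    for (a in 1:4) for (b in (a + 1):5) {
      inter <- sum(pres[, a] & pres[, b])
      expect_equal(d[a, b], 1 - 2 * inter / (sum(pres[, a]) + sum(pres[, b])),
                   tolerance = 1e-12)
    }
  }
})

test_that("PCoA embeds Euclidean configurations exactly", {
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  ord <- pcoa(D)
  expect_equal(unname(as.matrix(dist(ord$points[, 1]))), unname(D),
               tolerance = 1e-9)
  # regular simplex: all positive eigenvalues equal
  simplex <- matrix(1, 5, 5) - diag(5)
  rownames(simplex) <- colnames(simplex) <- letters[1:5]
  eig <- pcoa(simplex)$eig
  pos <- eig[eig > 1e-9]
  expect_equal(length(pos), 4)
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-9)
  # 2 samples: single axis separated by d
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  p2 <- pcoa(d2)
  expect_equal(unname(abs(diff(p2$points[, 1]))), 0.4, tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dropping negative-eigenvalue axes inflates distances consistently", {
  # squared dissimilarity decomposes as positive-part minus negative-part,
  # so the positive-axis embedding can only stretch distances; the
  # stretched squared distance minus the original equals the squared
  # separation on the (imaginary) negative axes
  set.seed(10)
  m <- matrix(rpois(80, 8) + 1, 10, 8)
  D <- as.matrix(bray_curtis(toy_table(m)))
  ord <- pcoa(D)
  emb <- as.matrix(dist(ord$points))
  expect_true(all(emb >= D - 1e-8))
  neg_total <- sum(abs(ord$eig[ord$eig < -1e-9]))
  expect_equal(sum(emb^2 - D^2) / (2 * nrow(D)), neg_total, tolerance = 1e-6)
})

test_that("PERMANOVA matches the stated sums of squares and an exhaustive p", {
  m <- matrix(c(0, 1, 4, 5,
                1, 0, 4.2, 5.1,
                4, 4.2, 0, 1.1,
                5, 5.1, 1.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  groups <- c("g1", "g1", "g2", "g2")
  res <- permanova(m, groups, n_perm = 99, seed = 1)
  bf <- permanova_bruteforce(m, groups)
  expect_equal(res$aov_tab$SS[1], bf$ss_a, tolerance = 1e-9)
  expect_equal(res$aov_tab$SS[2], bf$ss_within, tolerance = 1e-9)
  expect_equal(res$aov_tab$pseudo_F[1], bf$F, tolerance = 1e-9)
  expect_equal(res$aov_tab$R2[1], bf$R2, tolerance = 1e-9)
  # exhaustive: of the 6 distinct 2+2 labelings, only the observed one
  # separates the two tight pairs, so the exact p is 1/3; the sampled
  # permutation p must approach it
  res_big <- permanova(m, groups, n_perm = 9999, seed = 2)
  expect_equal(res_big$aov_tab$p[1], 1 / 3, tolerance = 0.03)
})

test_that("PERMANOVA agrees with vegan::adonis2 on R2 and F", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rpois(120, 10) + 1, 12, 10)
  tab <- toy_table(m)
  D <- bray_curtis(tab)
  groups <- rep(c("w", "d"), each = 5)
  res <- permanova(as.matrix(D)[1:10, 1:10], groups, n_perm = 49, seed = 1)
  ad <- vegan::adonis2(as.dist(as.matrix(D)[1:10, 1:10]) ~ groups,
                       permutations = 49)
  expect_equal(res$aov_tab$R2[1], ad$R2[1], tolerance = 1e-6)
  expect_equal(res$aov_tab$pseudo_F[1], ad$F[1], tolerance = 1e-6)
})

test_that("perfectly separated duplicate groups give R2 = 1", {
  m <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  m[1:3, 4:6] <- 1; m[4:6, 1:3] <- 1
  res <- permanova(m, rep(c("x", "y"), each = 3), n_perm = 99, seed = 3)
  expect_equal(res$aov_tab$R2[1], 1, tolerance = 1e-9)
})

test_that("CAP recovers a perfect two-cluster constraint and balances inertia", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 6), 5, 2))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:10)
  grp <- rep(c("A", "B"), each = 5)
  res <- cap(D, grp, n_perm = 999, seed = 4)
  # only label permutations preserving the two clusters tie the observed F
  expect_lt(res$p, 0.02)
  expect_equal(sum(res$inertia[c("constrained", "unconstrained")]),
               res$inertia[["total"]], tolerance = 1e-6)
  bf <- permanova_bruteforce(D, grp)
  expect_equal(res$constrained_fraction, bf$R2, tolerance = 1e-9)
  expect_error(cap(D, rep("A", 10)), "constant")
})

test_that("CAP constrained fraction tracks vegan::dbrda", {
  skip_if_not_installed("vegan")
  set.seed(14)
  m <- matrix(rpois(120, 10) + 1, 12, 10)
  D <- bray_curtis(toy_table(m))
  grp <- rep(c("w", "d"), 5)
  res <- cap(D, grp, n_perm = 49, seed = 1)
  vg <- vegan::dbrda(D ~ grp)
  expect_equal(res$constrained_fraction,
               vg$CCA$tot.chi / (vg$CCA$tot.chi + vg$CA$tot.chi),
               tolerance = 0.02)
})

test_that("Mantel statistic equals the lower-triangle correlation", {
  set.seed(15)
  m1 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  rownames(m1) <- colnames(m1) <- letters[1:5]
  res <- mantel_test(m1, m1, n_perm = 119, seed = 1)
  expect_equal(res$r, 1)
  res2 <- mantel_test(m1, 2 * m1, n_perm = 119, seed = 1)
  expect_equal(res2$r, 1)
  m2 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  rownames(m2) <- colnames(m2) <- letters[1:5]
  lt <- lower.tri(m1)
  expect_equal(mantel_test(m1, m2, n_perm = 9, seed = 1)$r,
               cor(m1[lt], m2[lt]), tolerance = 1e-12)
  # near-exhaustive permutation p agrees with vegan's Monte-Carlo estimate
  skip_if_not_installed("vegan")
  vr <- vegan::mantel(m1, m2, permutations = 119)
  expect_equal(mantel_test(m1, m2, n_perm = 119, seed = 2)$r, vr$statistic,
               tolerance = 1e-9)
  m3 <- m2; rownames(m3) <- colnames(m3) <- letters[2:6]
  expect_error(mantel_test(m1, m3), "ids differ")
})

test_that("single-factor R2 and residual share sum to one", {
  set.seed(16)
  m <- matrix(rpois(64, 12) + 1, 8, 8)
  D <- as.matrix(bray_curtis(toy_table(m)))
  res <- permanova(D, rep(c("x", "y"), 4), n_perm = 19, seed = 1)
  expect_equal(sum(res$aov_tab$R2), 1, tolerance = 1e-9)
})
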