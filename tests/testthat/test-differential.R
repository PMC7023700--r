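css_log_table <- function(m) {
  tab <- toy_table(m)
  css_normalize(tab, quantile = 0.5)
}

test_that("ZIG fit collapses to plain group means when there are no zeros", {
  set.seed(31)
  m <- matrix(rpois(10 * 12, 50) + 1, 10, 12)
  norm <- css_log_table(m)
  groups <- rep(c("wild", "domesticated"), each = 6)
  fit <- fit_zig(norm, groups)
  expect_true(all(fit$z == 0))
  y <- unclass(norm)
  expect_equal(unname(fit$group_means[, "wild"]),
               unname(rowMeans(y[, 1:6])), tolerance = 1e-6)
  expect_equal(unname(fit$group_means[, "domesticated"]),
               unname(rowMeans(y[, 7:12])), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("all-zero OTUs are excluded with a record", {
  set.seed(32)
  m <- matrix(rpois(8 * 10, 30) + 1, 8, 10)
  m[3, ] <- 0
  norm <- css_log_table(m)
  fit <- fit_zig(norm, rep(c("w", "d"), each = 5))
  expect_identical(fit$excluded, "otu3")
  expect_false("otu3" %in% rownames(fit$group_means))
})

test_that("depth-dependent technical zeros earn higher responsibilities", {
  # inject technical zeros preferentially into low-depth samples and
  # structural zeros independent of depth; the E-step should weight the
  # depth-driven zeros higher on average
  seeds_ok <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40; p <- 60
    depth <- exp(rnorm(n, 9, 0.7))
    m <- sapply(depth, function(d) rpois(p, d / p * runif(p, 0.3, 3)))
    rownames(m) <- sprintf("otu%d", 1:p); colnames(m) <- sprintf("s%d", 1:n)
    pr_tech <- 0.6 * (1 - rank(depth) / n)  # deeper samples lose fewer
    tech <- matrix(runif(p * n) < rep(pr_tech, each = p), p, n) & m > 0
    struct <- matrix(runif(p * n) < 0.1, p, n) & m > 0 & !tech
    m[tech] <- 0; m[struct] <- 0
    norm <- css_normalize(count_table(m, rep("bacteria", p)), quantile = 0.5)
    fit <- fit_zig(norm, rep(c("w", "d"), each = n / 2),
                   depth_covariate = log(colSums(m) + 1))
    if (mean(fit$z[tech]) >= mean(fit$z[struct])) seeds_ok <- seeds_ok + 1
  }
  expect_gte(seeds_ok, 7)
})

test_that("moderated t reproduces the shrinkage formula on a hand-checked toy", {
  set.seed(33)
  m <- matrix(rpois(6 * 6, 40) + 1, 6, 6)
  norm <- css_log_table(m)
  groups <- factor(rep(c("w", "d"), each = 3), levels = c("w", "d"))
  fit <- fit_zig(norm, groups)
  res <- moderated_t(fit, d0 = 4, s02 = 1)
  y <- unclass(norm)
  for (i in 1:6) {
    m1 <- mean(y[i, 1:3]); m2 <- mean(y[i, 4:6])
    s2 <- (sum((y[i, 1:3] - m1)^2) + sum((y[i, 4:6] - m2)^2)) / 4
    s2_post <- (4 * 1 + 4 * s2) / (4 + 4)
    t_hand <- (m2 - m1) / sqrt(s2_post * (1 / 3 + 1 / 3))
    expect_equal(res$moderated_t[i], t_hand, tolerance = 1e-6)
    expect_equal(res$p[i], 2 * pt(-abs(t_hand), df = 8), tolerance = 1e-6)
  }
  # d0 = 0 limit: ordinary two-sample pooled t
  res0 <- moderated_t(fit, d0 = 0, s02 = 1)
  tt <- apply(y, 1, function(v)
    t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic)
  expect_equal(res0$moderated_t, unname(tt), tolerance = 1e-6)
})

test_that("moderated t p-values are calibrated under the null", {
  set.seed(34)
  pvals <- c()
  for (rep in 1:3) {
    p <- 120; n <- 30
    y <- matrix(rnorm(p * n, mean = 8), p, n,
                dimnames = list(sprintf("otu%d", 1:p), sprintf("s%d", 1:n)))
    norm <- seedmb:::new_norm_table(y, "css_log",
                           scale_factors = setNames(rep(1000, n), colnames(y)))
    fit <- fit_zig(norm, rep(c("w", "d"), each = n / 2))
    pvals <- c(pvals, moderated_t(fit)$p)
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(35)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment categories follow the fold-change/FDR rule", {
  rec <- data.frame(otu_id = c("a", "b", "c", "d"),
                    log2_fold_change = c(2.5, 2.5, -3, 1),
                    p = c(1e-4, 0.5, 1e-6, 0.2))
  out <- classify_enrichment(rec, q = c(0.005, 0.02, 1e-5, 0.3))
  expect_identical(out$category,
                   c("domesticated_enriched", "non_differential",
                     "wild_enriched", "non_differential"))
})

test_that("core OTU prevalence is counted at accession level", {
  # 10 accessions x 3 replicates; otu1 present in 4/5... pattern by hand
  acc <- rep(sprintf("a%02d", 1:5), each = 3)
  m <- matrix(0L, 2, 15,
              dimnames = list(c("otu1", "otu2"), sprintf("s%d", 1:15)))
  m["otu1", c(1, 4, 8, 12)] <- 5L   # accessions 1,2,3,4 -> prevalence 0.8
  m["otu2", c(1, 2, 3)] <- 2L       # accession 1 only -> prevalence 0.2
  tab <- count_table(m, c("bacteria", "bacteria"))
  cs80 <- core_otus(tab, acc, 0.8)
  expect_identical(cs80$otu_ids, "otu1")
  cs95 <- core_otus(tab, acc, 0.95)
  expect_identical(cs95$otu_ids, character(0))
  expect_equal(unname(cs80$prevalence), c(0.8, 0.2))
  # requiring >=2 replicate detections drops otu1
  cs_rep2 <- core_otus(tab, acc, 0.8, min_replicates = 2)
  expect_identical(cs_rep2$otu_ids, character(0))
})

test_that("hand-built 10x3 presence pattern matches manual prevalence tally", {
  set.seed(36)
  acc <- rep(sprintf("a%02d", 1:10), each = 3)
  m <- matrix(rbinom(20 * 30, 1, 0.5) * rpois(20 * 30, 3), 20, 30,
              dimnames = list(sprintf("otu%d", 1:20), sprintf("s%d", 1:30)))
  tab <- count_table(m, rep("bacteria", 20))
  cs <- core_otus(tab, acc, 0.8)
  manual <- sapply(1:20, function(i) {
    pres <- tapply(m[i, ] > 0, acc, any)
    mean(pres)
  })
  expect_equal(unname(cs$prevalence), unname(manual))
  expect_setequal(cs$otu_ids, rownames(m)[manual >= 0.8])
})
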