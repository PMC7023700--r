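# count fixture: independent log-normal basis abundances with optional
# duplicated rows, closed to fractions and sampled multinomially
sparcc_fixture <- function(p, n, depth = 20000, sigma = 1, dup = NULL,
                           seed = 1) {
  set.seed(seed + 5000)
  basis <- exp(matrix(rnorm(p * n, 0, sigma), p, n) + rnorm(p, 0, 1))
  if (!is.null(dup)) basis[dup[2], ] <- basis[dup[1], ]
  frac <- sweep(basis, 2, colSums(basis), "/")
  counts <- sapply(seq_len(n), function(j) rmultinom(1, depth, frac[, j])[, 1])
  rownames(counts) <- sprintf("otu%d", seq_len(p))
  colnames(counts) <- sprintf("s%d", seq_len(n))
  counts
}

test_that("the vectorized row median matches the scalar definition", {
  set.seed(50)
  for (k in c(1, 2, 3, 5, 20)) {
    m <- matrix(rnorm(500 * k), 500, k)
    expect_equal(seedmb:::row_medians(m), apply(m, 1, median), tolerance = 1e-12)
  }
})

test_that("SparCC recovers an identical pair and rejects tiny systems", {
  rhos <- vapply(1:5, function(s) {
    counts <- sparcc_fixture(8, 60, dup = c(1, 2), seed = s)
    sparcc(toy_table(counts), n_iter = 10, seed = s)$rho[1, 2]
  }, numeric(1))
  expect_gt(median(rhos), 0.9)
  counts <- sparcc_fixture(3, 20, seed = 1)
  expect_error(sparcc(toy_table(counts)), "4 OTUs")
})

test_that("SparCC null |rho| stays at the correlation noise floor", {
  # at n samples no correlation estimator can push the null mean |rho|
  # below the Pearson floor sqrt(2/pi)/sqrt(n - 1); SparCC must sit at or
  # near that floor and produce no spurious strong correlations
  n <- 200
  counts <- sparcc_fixture(50, n, seed = 2)
  est <- sparcc(toy_table(counts), n_iter = 10, seed = 1)
  off <- est$rho[upper.tri(est$rho)]
  floor_abs <- sqrt(2 / pi) / sqrt(n - 1)
  expect_lt(mean(abs(off)), 1.15 * floor_abs)
  expect_lt(max(abs(off)), 0.3)
})

test_that("pseudo p-values floor on extreme pairs and stay symmetric", {
  tab <- toy_table(sparcc_fixture(8, 50, dup = c(1, 2), seed = 3))
  est <- sparcc(tab, n_iter = 10, seed = 1)
  pp <- sparcc_pseudo_p(tab, est$rho, n_boot = 30, null_n_iter = 3, seed = 2)
  expect_equal(pp[1, 2], 1 / 31)
  expect_true(all(is.na(diag(pp))))
  expect_equal(pp, t(pp))
  expect_warning(sparcc_pseudo_p(tab, est$rho, n_boot = 10, null_n_iter = 2,
                                 seed = 3), "coarse")
})

test_that("network building applies both thresholds literally", {
  rho <- diag(5)
  dimnames(rho) <- list(sprintf("o%d", 1:5), sprintf("o%d", 1:5))
  pp <- matrix(1, 5, 5, dimnames = dimnames(rho)); diag(pp) <- NA
  rho["o1", "o2"] <- rho["o2", "o1"] <- 0.5
  pp["o1", "o2"] <- pp["o2", "o1"] <- 0.01
  rho["o3", "o4"] <- rho["o4", "o3"] <- 0.5
  pp["o3", "o4"] <- pp["o4", "o3"] <- 0.2  # fails the p filter
  rho["o1", "o5"] <- rho["o1", "o5"] <- 0.2 # fails the r filter
  kingdoms <- setNames(rep("bacteria", 5), rownames(rho))
  net <- build_network(rho, pp, kingdoms)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes$otu_id, c("o1", "o2"))
  expect_setequal(net$isolated, c("o3", "o4", "o5"))
  # boundary: |rho| must strictly exceed the threshold
  rho2 <- rho; rho2["o1", "o2"] <- rho2["o2", "o1"] <- 0.3
  expect_equal(nrow(build_network(rho2, pp, kingdoms)$edges), 0)
})

test_that("centralities match closed forms and brute force", {
  star_rho <- diag(5); dimnames(star_rho) <- list(letters[1:5], letters[1:5])
  pp <- matrix(0.001, 5, 5, dimnames = dimnames(star_rho))
  for (l in 2:5) star_rho[1, l] <- star_rho[l, 1] <- 0.9
  net <- build_network(star_rho, pp, setNames(rep("bacteria", 5), letters[1:5]))
  cent <- centralities(net)
  expect_equal(cent$degree[cent$otu_id == "a"], 4)
  expect_equal(sort(cent$degree[cent$otu_id != "a"]), rep(1, 4))
  expect_equal(cent$betweenness[cent$otu_id == "a"], 1)
  expect_equal(max(cent$betweenness[cent$otu_id != "a"]), 0)
  # path a-b-c
  path_rho <- diag(3); dimnames(path_rho) <- list(c("a", "b", "c"), c("a", "b", "c"))
  path_rho["a", "b"] <- path_rho["b", "a"] <- 0.8
  path_rho["b", "c"] <- path_rho["c", "b"] <- 0.8
  pp3 <- matrix(0.001, 3, 3, dimnames = dimnames(path_rho))
  net3 <- build_network(path_rho, pp3, setNames(rep("fungi", 3), c("a", "b", "c")))
  c3 <- centralities(net3)
  expect_equal(c3$betweenness[c3$otu_id == "b"], 1)

  # arbitrary 7-node graphs vs brute-force shortest-path enumeration
  set.seed(54)
  for (i in 1:5) {
    repeat {
      adj <- matrix(0, 7, 7)
      adj[upper.tri(adj)] <- rbinom(21, 1, 0.4)
      adj <- adj + t(adj)
      if (all(rowSums(adj) > 0)) break
    }
    dimnames(adj) <- list(letters[1:7], letters[1:7])
    rho <- adj * 0.9; diag(rho) <- 1
    ppm <- ifelse(adj > 0, 0.001, 1); diag(ppm) <- NA
    net7 <- build_network(rho, ppm, setNames(rep("bacteria", 7), letters[1:7]))
    cent7 <- centralities(net7)
    bf <- betweenness_bruteforce(adj)
    expect_equal(cent7$betweenness[match(letters[1:7], cent7$otu_id)], bf,
                 tolerance = 1e-9)
  }
})

test_that("hub detection uses strict top-percentile cutoffs", {
  # 20-node star: the centre is the only node exceeding both cutoffs
  n <- 20
  rho <- diag(n); dimnames(rho) <- list(sprintf("o%d", 1:n), sprintf("o%d", 1:n))
  pp <- matrix(0.001, n, n, dimnames = dimnames(rho))
  for (l in 2:n) rho[1, l] <- rho[l, 1] <- 0.9
  net <- build_network(rho, pp, setNames(rep("bacteria", n), rownames(rho)))
  hubs <- detect_hubs(net, percentile = 0.05)
  expect_identical(hubs$hubs, "o1")
  # all-identical centralities: nobody strictly exceeds the quantile
  rho2 <- diag(4); dimnames(rho2) <- list(letters[1:4], letters[1:4])
  rho2[1, 2] <- rho2[2, 1] <- rho2[3, 4] <- rho2[4, 3] <- 0.9
  pp2 <- matrix(0.001, 4, 4, dimnames = dimnames(rho2))
  net2 <- build_network(rho2, pp2, setNames(rep("fungi", 4), letters[1:4]))
  expect_length(detect_hubs(net2, 0.02)$hubs, 0)
})

test_that("hub detection is invariant to node relabeling", {
  set.seed(55)
  n <- 12
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.3)
  adj <- adj + t(adj); adj[1, 2:6] <- adj[2:6, 1] <- 1
  ids <- sprintf("o%02d", 1:n)
  make_net <- function(order_idx) {
    a <- adj[order_idx, order_idx]
    rho <- a * 0.8; diag(rho) <- 1
    dimnames(rho) <- list(ids[order_idx], ids[order_idx])
    pp <- ifelse(a > 0, 0.001, 1); diag(pp) <- NA; dimnames(pp) <- dimnames(rho)
    build_network(rho, pp, setNames(rep("bacteria", n), ids[order_idx]))
  }
  h1 <- detect_hubs(make_net(1:n), 0.1)
  h2 <- detect_hubs(make_net(sample(n)), 0.1)
  expect_setequal(h1$hubs, h2$hubs)
})

test_that("kingdom edge shares are complete and sum to one", {
  rho <- diag(4); dimnames(rho) <- list(c("B1", "B2", "F1", "F2"),
                                        c("B1", "B2", "F1", "F2"))
  rho["B1", "B2"] <- rho["B2", "B1"] <- 0.8
  rho["B1", "F1"] <- rho["F1", "B1"] <- -0.8
  pp <- matrix(0.001, 4, 4, dimnames = dimnames(rho))
  kd <- setNames(c("bacteria", "bacteria", "fungi", "fungi"), rownames(rho))
  net <- build_network(rho, pp, kd)
  shares <- kingdom_edge_proportions(net)
  expect_equal(sum(shares), 1)
  expect_equal(shares[["BB_positive"]], 0.5)
  expect_equal(shares[["BF_negative"]], 0.5)
  # all-bacterial graph
  net_b <- build_network(rho[1:2, 1:2], pp[1:2, 1:2], kd[1:2])
  expect_equal(kingdom_edge_proportions(net_b)[["BB_positive"]], 1)
})
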