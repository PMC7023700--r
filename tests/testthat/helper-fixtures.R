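# shared in-code fixtures and independent oracles

toy_table <- function(counts, kingdom = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) rownames(m) <- sprintf("otu%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(kingdom)) kingdom <- rep("bacteria", nrow(m))
  count_table(m, kingdom)
}

# mean-absolute-difference Gini by full pair enumeration
gini_bruteforce <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# trapezoidal area under the Lorenz curve -> Gini
gini_lorenz_area <- function(x) {
  xs <- sort(x)
  L <- c(0, cumsum(xs) / sum(xs))
  p <- c(0, seq_along(xs) / length(xs))
  area <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  1 - 2 * area
}

# brute-force Robinson-Foulds via explicit bipartition label sets
rf_bruteforce <- function(t1, t2, normalized = TRUE) {
  splits_of <- function(tr) {
    tr <- ape::unroot(tr)
    labs <- sort(tr$tip.label)
    n <- length(labs)
    parts <- ape::prop.part(tr)
    out <- character(0)
    for (p in parts) {
      side <- sort(tr$tip.label[p])
      if (length(side) < 2 || length(side) > n - 2) next
      if (labs[1] %in% side) side <- sort(setdiff(labs, side))
      out <- c(out, paste(side, collapse = "|"))
    }
    unique(out)
  }
  s1 <- splits_of(t1); s2 <- splits_of(t2)
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (!normalized) raw else if (length(s1) + length(s2) == 0) 0 else
    raw / (length(s1) + length(s2))
}

# brute-force betweenness: enumerate all shortest paths between all pairs
betweenness_bruteforce <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(a, b) {
    # BFS shortest-path enumeration
    best <- Inf; found <- list()
    queue <- list(a)
    while (length(queue)) {
      path <- queue[[1]]; queue <- queue[-1]
      v <- path[length(path)]
      if (length(path) - 1 > best) next
      if (v == b) {
        if (length(path) - 1 < best) { best <- length(path) - 1; found <- list() }
        found[[length(found) + 1]] <- path
        next
      }
      for (w in which(adj[v, ] == 1)) if (!(w %in% path))
        queue[[length(queue) + 1]] <- c(path, w)
    }
    found
  }
  btw <- numeric(n)
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    paths <- all_paths(a, b)
    if (!length(paths)) next
    for (p in paths) {
      inner <- p[-c(1, length(p))]
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# PERMANOVA sums of squares from the stated group formulas
permanova_bruteforce <- function(m, groups) {
  n <- nrow(m)
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_a <- ss_total - ss_within
  a <- length(unique(groups))
  Fv <- (ss_a / (a - 1)) / (ss_within / (n - a))
  list(ss_total = ss_total, ss_a = ss_a, ss_within = ss_within,
       F = Fv, R2 = ss_a / ss_total)
}

# AUC by explicit positive-negative pair enumeration
auc_bruteforce <- function(scores, labels) {
  labels <- factor(labels)
  pos <- scores[labels == levels(labels)[2]]
  neg <- scores[labels == levels(labels)[1]]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# BH step-up by the min-over-j definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(k) min(1, ps[k:m] * m / (k:m)),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}
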