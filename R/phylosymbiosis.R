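#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage hierarchical clustering, returned as an `ape::phylo`
#' tree. Ids are ordered lexicographically before clustering so that ties
#' are broken deterministically by label order.
#'
#' @param D distance matrix (`dist` or symmetric matrix) with >= 3 ids.
#' @return an ultrametric `phylo` tree.
#' @export
upgma_dendrogram <- function(D) {
  m <- as_dist_matrix(D)
  if (any(is.na(m)) || any(!is.finite(m))) stop("non-finite distances")
  if (nrow(m) < 3) stop("need at least 3 ids")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}

# Non-trivial splits of an unrooted tree as a list of tip-index sets
# (indices into `labels`), each canonicalized to the side not containing
# the first label.
tree_splits <- function(tree, labels) {
  if (!all(sort(tree$tip.label) == sort(labels)))
    stop("leaf-set mismatch: ",
         paste(c(setdiff(labels, tree$tip.label),
                 setdiff(tree$tip.label, labels)), collapse = ", "))
  n <- length(labels)
  tr <- ape::unroot(tree)
  idx <- match(tr$tip.label, labels)
  parts <- ape::prop.part(tr)
  splits <- lapply(parts, function(p) sort(idx[p]))
  keep <- vapply(splits, function(s) length(s) >= 2 && length(s) <= n - 2,
                 logical(1))
  splits <- splits[keep]
  canon <- lapply(splits, function(s) if (1 %in% s) sort(setdiff(seq_len(n), s)) else s)
  unique(canon)
}

split_keys <- function(splits) {
  vapply(splits, function(s) paste(s, collapse = ","), character(1))
}

#' Robinson-Foulds distance between two leaf trees
#'
#' Symmetric-difference count of the non-trivial unrooted bipartitions of
#' the two trees; with `normalized = TRUE`, divided by the maximum
#' attainable (the total number of non-trivial splits in the two trees,
#' `2(n-3)` when both are fully resolved).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @param normalized return the normalized score in `[0, 1]`.
#' @return RF distance (count or normalized fraction).
#' @export
robinson_foulds <- function(t1, t2, normalized = TRUE) {
  labels <- sort(t1$tip.label)
  s1 <- split_keys(tree_splits(t1, labels))
  s2 <- split_keys(tree_splits(t2, labels))
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (!normalized) return(raw)
  denom <- length(s1) + length(s2)
  if (denom == 0) return(0)
  raw / denom
}

#' Phylosymbiosis test by Robinson-Foulds congruence against random trees
#'
#' Compares the host phylogeny with a microbial community dendrogram sharing
#' its leaves. The observed normalized RF score is ranked within a null
#' ensemble of randomized trees: either the dendrogram with leaf labels
#' shuffled (`"label_shuffle"`, shape-preserving, the default) or uniformly
#' random binary topologies (`"random_topology"`). The p-value is the
#' add-one fraction of null trees at least as congruent as observed,
#' `p = (1 + #{RF_null <= RF_obs}) / (n_random + 1)`.
#'
#' @param host host `phylo` tree.
#' @param dendro community dendrogram (`phylo`), same leaf set.
#' @param n_random number of randomized trees.
#' @param null_model `"label_shuffle"` or `"random_topology"`.
#' @param seed RNG seed.
#' @return object of class `phylosymbiosis` with `rf_observed`,
#'   `null_scores`, `p`, `n_random`, `null_model`.
#' @export
phylosymbiosis_test <- function(host, dendro, n_random = 1000,
                                null_model = c("label_shuffle", "random_topology"),
                                seed = NULL) {
  null_model <- match.arg(null_model)
  labels <- sort(host$tip.label)
  n <- length(labels)
  if (n < 4) stop("need at least 4 shared leaves")
  if (n_random < 100) warning("n_random < 100 gives a coarse null")
  host_splits <- tree_splits(host, labels)
  dend_splits <- tree_splits(dendro, labels)
  denom_obs <- length(host_splits) + length(dend_splits)
  host_keys <- split_keys(host_splits)
  shared <- sum(split_keys(dend_splits) %in% host_keys)
  rf_obs <- if (denom_obs == 0) 0 else (denom_obs - 2 * shared) / denom_obs
  if (!is.null(seed)) set.seed(seed)
  null_scores <- numeric(n_random)
  if (null_model == "label_shuffle" && n <= 52) {
    # exact double-precision bitmask encoding of splits (n <= 52 tips);
    # a split and its complement are canonicalized to the smaller mask
    pow2 <- 2^(seq_len(n) - 1)
    full_mask <- sum(pow2)
    canon <- function(m) pmin(m, full_mask - m)
    host_masks <- canon(vapply(host_splits, function(s) sum(pow2[s]),
                               numeric(1)))
    S <- matrix(0, length(dend_splits), n)  # split x tip incidence
    for (k in seq_along(dend_splits)) S[k, dend_splits[[k]]] <- 1
    for (b in seq_len(n_random)) {
      perm <- sample.int(n)
      masks <- canon(as.vector(S[, perm, drop = FALSE] %*% pow2))
      sh <- sum(masks %in% host_masks)
      null_scores[b] <- (denom_obs - 2 * sh) / denom_obs
    }
  } else if (null_model == "label_shuffle") {
    host_set <- new.env(hash = TRUE, size = length(host_keys) * 2 + 1)
    for (k in host_keys) assign(k, TRUE, envir = host_set)
    full <- seq_len(n)
    for (b in seq_len(n_random)) {
      perm <- sample.int(n)
      sh <- 0L
      for (s in dend_splits) {
        ps <- sort(perm[s])
        if (ps[1] == 1L) ps <- setdiff(full, ps)
        if (exists(paste(ps, collapse = ","), envir = host_set, inherits = FALSE))
          sh <- sh + 1L
      }
      null_scores[b] <- (denom_obs - 2 * sh) / denom_obs
    }
  } else {
    for (b in seq_len(n_random)) {
      rt <- ape::rtopology(n, rooted = FALSE, tip.label = labels)
      rs <- tree_splits(rt, labels)
      sh <- sum(split_keys(rs) %in% host_keys)
      dn <- length(host_splits) + length(rs)
      null_scores[b] <- if (dn == 0) 0 else (dn - 2 * sh) / dn
    }
  }
  p <- (1 + sum(null_scores <= rf_obs + 1e-12)) / (n_random + 1)
  structure(list(rf_observed = rf_obs, null_scores = null_scores, p = p,
                 n_random = n_random, null_model = null_model, seed = seed),
            class = "phylosymbiosis")
}

#' @export
print.phylosymbiosis <- function(x, ...) {
  cat("Phylosymbiosis RF congruence test (", x$null_model, " null, ",
      x$n_random, " randomized trees)\n", sep = "")
  cat("  normalized RF =", format(x$rf_observed, digits = 4),
      " p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Pair host and dendrogram leaves for a tanglegram
#'
#' @param host,dendro `phylo` trees over the same leaf set.
#' @return list with both trees and a data.frame `association` pairing each
#'   leaf with itself (the cophylo-style association table).
#' @export
cophylogeny_report <- function(host, dendro) {
  labels <- sort(host$tip.label)
  tree_splits(dendro, labels)  # validates shared leaf set
  list(host = host, dendro = dendro,
       association = data.frame(host = labels, dendro = labels))
}
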