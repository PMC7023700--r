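#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over samples (columns) of a
#' count or normalized table; `binary = TRUE` first reduces values to
#' presence/absence, giving the Sorensen dissimilarity of the presence sets.
#'
#' @param table [count_table()] or `norm_table` (samples in columns).
#' @param binary use presence/absence.
#' @return a `dist` object with attribute `metric`.
#' @export
bray_curtis <- function(table, binary = FALSE) {
  m <- t(table_values(table))
  if (nrow(m) < 2) stop("need at least two samples")
  empty <- rowSums(m) == 0
  if (sum(empty) >= 2)
    stop("all-zero samples give undefined distances: ",
         paste(rownames(m)[empty], collapse = ", "))
  d <- vegan::vegdist(m, method = "bray", binary = binary)
  attr(d, "metric") <- if (binary) "bray_curtis_binary" else "bray_curtis"
  d
}

as_dist_matrix <- function(D) {
  m <- as.matrix(D)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  m
}

#' Principal coordinates analysis
#'
#' Classical (Gower) scaling of a distance matrix. All eigenvalues,
#' including negative ones, are reported.
#'
#' @param D distance matrix (`dist` or symmetric matrix).
#' @return list with `points` (samples x axes, positive-eigenvalue axes),
#'   `eig` (all eigenvalues, decreasing) and `prop_explained` over positive
#'   eigenvalues.
#' @export
pcoa <- function(D) {
  m <- as_dist_matrix(D)
  n <- nrow(m)
  # cmdscale warns when k exceeds the number of positive eigenvalues,
  # which is routine for Bray-Curtis input; eigenvalues are reported anyway
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-9)
  pts <- fit$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_along(pos))
  list(points = pts, eig = eig,
       prop_explained = eig[pos] / sum(eig[pos]))
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities
#' `SS_total = (1/n) * sum_{i<j} d_ij^2` among one or more factors using the
#' Gower-centred inner-product matrix; with several factors, sequential sums
#' of squares in the order given. Significance is assessed by permuting
#' sample labels, with the add-one convention
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param D distance matrix.
#' @param groups factor (or data.frame of factors for a sequential
#'   multi-factor model) aligned with the rows of `D`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return object of class `permanova`: data.frame `aov_tab` with per-factor
#'   `df`, `SS`, `R2`, `pseudo_F`, `p`, plus `n_perm` and `seed`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(D)
  n <- nrow(m)
  df_groups <- if (is.data.frame(groups)) groups else data.frame(factor = groups)
  df_groups[] <- lapply(df_groups, factor)
  if (nrow(df_groups) != n) stop("groups must align with the distance matrix")
  for (nm in names(df_groups)) {
    tab <- table(df_groups[[nm]])
    if (any(tab == 0) || length(tab) < 2)
      stop("factor '", nm, "' needs >=2 non-empty groups")
  }
  stopifnot(n_perm >= 1)
  G <- gower_center(m)
  ss_total <- sum(diag(G))
  hats <- sequential_hats(df_groups)
  stat <- function(Gm) {
    expl <- vapply(hats$H, function(H) sum(H * Gm), numeric(1))
    ss_seq <- diff(c(0, expl))
    ss_res <- ss_total - expl[length(expl)]
    Fv <- (ss_seq / hats$df) / (ss_res / hats$df_res)
    list(ss = ss_seq, ss_res = ss_res, F = Fv)
  }
  obs <- stat(G)
  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(obs$F))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Fp <- stat(G[p, p])$F
    exceed <- exceed + (Fp >= obs$F - 1e-12)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  aov_tab <- data.frame(
    factor = names(df_groups), df = hats$df, SS = obs$ss,
    R2 = obs$ss / ss_total,
    pseudo_F = obs$F, p = pvals, row.names = NULL)
  res <- rbind(aov_tab,
               data.frame(factor = "Residual", df = hats$df_res,
                          SS = obs$ss_res, R2 = obs$ss_res / ss_total,
                          pseudo_F = NA, p = NA))
  structure(list(aov_tab = res, SS_total = ss_total, n_perm = n_perm,
                 seed = seed), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_perm, " permutations",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  print(x$aov_tab, digits = 4)
  invisible(x)
}

gower_center <- function(m) {
  A <- -0.5 * m^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Hat matrices of the sequential model sequence ~1+f1, ~1+f1+f2, ...
sequential_hats <- function(df_groups) {
  n <- nrow(df_groups)
  H <- list(); dfs <- numeric(0)
  prev_rank <- 1
  for (k in seq_along(df_groups)) {
    X <- stats::model.matrix(~ ., df_groups[seq_len(k)])
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    H[[k]] <- tcrossprod(Q)
    dfs[k] <- qrX$rank - prev_rank
    prev_rank <- qrX$rank
  }
  list(H = H, df = dfs, df_res = n - prev_rank)
}

#' Constrained analysis of principal coordinates (distance-based RDA)
#'
#' PCoA axes with positive eigenvalues are regressed on the constraint's
#' dummy variables; the constrained inertia is the sum of squares of the
#' fitted values. Axes with negative eigenvalues are excluded from the
#' ordination and their total magnitude reported. Significance is a
#' permutation test of the pseudo-F of constrained vs residual inertia
#' (add-one convention).
#'
#' @param D distance matrix.
#' @param constraint factor (or data.frame of factors) per sample.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return object of class `cap_result` with constrained axis coordinates,
#'   `inertia` components and permutation `p`.
#' @export
cap <- function(D, constraint, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(D)
  n <- nrow(m)
  df_c <- if (is.data.frame(constraint)) constraint else data.frame(constraint = constraint)
  df_c[] <- lapply(df_c, factor)
  if (any(vapply(df_c, nlevels, 1L) < 2)) stop("constant constraint")
  ord <- pcoa(m)
  Y <- ord$points  # column-centred by construction
  neg_inertia <- sum(abs(ord$eig[ord$eig < 0]))
  X <- stats::model.matrix(~ ., df_c)
  qrX <- qr(X)
  df_model <- qrX$rank - 1
  df_res <- n - qrX$rank
  total <- sum(Y^2)
  constrained <- sum(qr.fitted(qrX, Y)^2)
  unconstrained <- total - constrained
  Fobs <- (constrained / df_model) / (unconstrained / df_res)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    cp <- sum(qr.fitted(qrX, Yp)^2)
    Fp <- (cp / df_model) / ((total - cp) / df_res)
    exceed <- exceed + (Fp >= Fobs - 1e-12)
  }
  # constrained axis scores: eigen decomposition of fitted values
  Fhat <- qr.fitted(qrX, Y)
  r <- min(df_model, ncol(Y))
  sv <- svd(Fhat, nu = r)
  keep <- which(sv$d[seq_len(r)] > max(sv$d) * 1e-9)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("CAP", seq_len(ncol(scores)))
  structure(list(scores = scores,
                 inertia = c(total = total, constrained = constrained,
                             unconstrained = unconstrained,
                             negative_ignored = neg_inertia),
                 constrained_fraction = constrained / total,
                 pseudo_F = Fobs, df = c(model = df_model, residual = df_res),
                 p = (1 + exceed) / (n_perm + 1), n_perm = n_perm, seed = seed),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat("CAP / db-RDA: constrained fraction ",
      format(x$constrained_fraction, digits = 4),
      ", pseudo-F ", format(x$pseudo_F, digits = 4),
      ", p = ", format(x$p, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) over lower-triangle entries;
#' significance by jointly permuting rows and columns of the second matrix
#' (one-sided, add-one convention).
#'
#' @param D1,D2 distance matrices over the same ids in the same order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(D1, D2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  m1 <- as_dist_matrix(D1); m2 <- as_dist_matrix(D2)
  if (!identical(dim(m1), dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("distance matrix ids differ: ",
         paste(setdiff(rownames(m1), rownames(m2)), collapse = ", "))
  lt <- lower.tri(m1)
  r_obs <- stats::cor(m1[lt], m2[lt], method = method)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m1)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(m1[lt], m2[p, p][lt], method = method)
    exceed <- exceed + (rp >= r_obs - 1e-12)
  }
  list(r = r_obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm, seed = seed)
}

#' Write / read a square distance matrix TSV
#'
#' @param D distance matrix.
#' @param path file path.
#' @return `path` (write) or a matrix (read).
#' @export
write_distance <- function(D, path) {
  m <- as_dist_matrix(D)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  as_dist_matrix(m)
}
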