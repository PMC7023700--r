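#' SparCC compositionality-robust correlation estimate
#'
#' Estimates correlations between underlying (basis) abundances from
#' compositional counts. Per outer iteration, sample fractions are drawn
#' from a Dirichlet posterior (counts + 1); the variation matrix
#' `t_ij = var(log(x_i / x_j))` is formed; basis variances `omega` are
#' solved from the sparsity approximation
#' `sum_j t_ij = (p - 2) * omega_i + sum_j omega_j`; and basis correlations
#' are `rho_ij = (omega_i + omega_j - t_ij) / (2 * sqrt(omega_i * omega_j))`.
#' An inner loop repeatedly excludes the currently strongest-correlated
#' pair (while it exceeds `exclusion_threshold`) and re-solves, up to
#' `n_inner` rounds. The final estimate is the elementwise median over
#' `n_iter` outer iterations.
#'
#' @param table a [count_table()] (or count matrix, OTUs in rows).
#' @param n_iter outer Dirichlet-resampling iterations (default 20).
#' @param n_inner maximum strong-pair exclusion rounds (default 10).
#' @param exclusion_threshold |rho| above which pairs keep being excluded.
#' @param seed RNG seed.
#' @return object of class `sparcc_estimate`: `rho`, `variation` (median
#'   t matrix), `omega`, `n_iter`, `clipped` (count of |rho| clip events),
#'   `negative_omega` (count of clamped basis variances).
#' @export
sparcc <- function(table, n_iter = 20, n_inner = 10,
                   exclusion_threshold = 0.1, seed = NULL) {
  counts <- table_values(table)
  p <- nrow(counts); n <- ncol(counts)
  if (p < 4) stop("SparCC needs at least 4 OTUs (system underdetermined)")
  if (n < 4) stop("SparCC needs at least 4 samples")
  if (!is.null(seed)) set.seed(seed)
  rhos <- array(NA_real_, c(p, p, n_iter))
  ts <- array(NA_real_, c(p, p, n_iter))
  omegas <- matrix(NA_real_, p, n_iter)
  clipped <- 0L; neg_omega <- 0L
  for (it in seq_len(n_iter)) {
    # Dirichlet(counts + 1) fractions per sample
    g <- matrix(stats::rgamma(p * n, shape = counts + 1), p, n)
    frac <- sweep(g, 2, colSums(g), "/")
    lf <- log(frac)
    V <- stats::cov(t(lf))
    Tm <- outer(diag(V), diag(V), "+") - 2 * V
    est <- sparcc_basis(Tm, n_inner, exclusion_threshold)
    clipped <- clipped + est$clipped
    neg_omega <- neg_omega + est$neg_omega
    rhos[, , it] <- est$rho
    ts[, , it] <- Tm
    omegas[, it] <- est$omega
  }
  rho <- matrix(row_medians(matrix(rhos, p * p, n_iter)), p, p)
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  structure(list(rho = rho,
                 variation = matrix(row_medians(matrix(ts, p * p, n_iter)),
                                    p, p),
                 omega = stats::setNames(row_medians(omegas),
                                         rownames(counts)),
                 n_iter = n_iter, clipped = clipped,
                 negative_omega = neg_omega),
            class = "sparcc_estimate")
}

# vectorized per-row median via a pmin/pmax sorting network; the column
# count (outer iteration count) is small, so the O(k^2) network is cheap
row_medians <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k == 1) return(m[, 1])
  for (i in seq_len(k - 1)) for (j in seq_len(k - i)) {
    a <- m[, j]; b <- m[, j + 1]
    m[, j] <- pmin(a, b); m[, j + 1] <- pmax(a, b)
  }
  if (k %% 2 == 1) m[, (k + 1) / 2] else (m[, k / 2] + m[, k / 2 + 1]) / 2
}

# One basis-variance solve with iterative strong-pair exclusion.
sparcc_basis <- function(Tm, n_inner, exclusion_threshold) {
  p <- nrow(Tm)
  M <- matrix(1, p, p); diag(M) <- p - 1
  Tmask <- Tm
  excluded <- matrix(FALSE, p, p)
  neg_omega <- 0L; clipped <- 0L
  solve_rho <- function() {
    omega <- solve(M, rowSums(Tmask))
    nneg <- sum(omega <= 0)
    omega <- pmax(omega, 1e-12)
    rho <- (outer(omega, omega, "+") - Tm) / (2 * sqrt(outer(omega, omega)))
    nclip <- sum(abs(rho) > 1) - p  # diagonal is exactly 1
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    list(omega = omega, rho = rho, nneg = nneg, nclip = max(nclip, 0L))
  }
  est <- solve_rho()
  for (round in seq_len(n_inner)) {
    cand <- abs(est$rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    # removing a pair from the averaging: drop its t entry and its unit
    # contribution on both rows of the linear system
    if (M[i, i] <= 2 || M[j, j] <= 2) break  # keep system well-posed
    excluded[i, j] <- excluded[j, i] <- TRUE
    Tmask[i, j] <- Tmask[j, i] <- 0
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    est <- solve_rho()
  }
  if (est$nneg > 0) neg_omega <- est$nneg
  list(rho = est$rho, omega = est$omega, clipped = est$nclip,
       neg_omega = neg_omega, excluded = excluded)
}

#' @export
print.sparcc_estimate <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat("SparCC estimate over", nrow(x$rho), "OTUs (median of", x$n_iter,
      "iterations)\n")
  cat("  |rho| quantiles:",
      paste(format(stats::quantile(abs(off), c(.5, .9, 1)), digits = 3),
            collapse = " / "), "(50/90/100%)\n")
  invisible(x)
}

#' Pseudo p-values for SparCC correlations
#'
#' Null datasets are formed by independently permuting each OTU's counts
#' across samples (`mode = "permute"`, destroying correlation while
#' preserving marginals) or by resampling samples with replacement
#' (`mode = "bootstrap"`); SparCC is recomputed on each (with a reduced
#' `null_n_iter`) and the two-sided pseudo p-value is
#' `p_ij = (1 + #{|rho_null| >= |rho_obs|}) / (n_boot + 1)`.
#'
#' @param table the [count_table()] used for the observed estimate.
#' @param rho_obs observed correlation matrix from [sparcc()].
#' @param n_boot null replicates (default 100).
#' @param null_n_iter outer iterations per null replicate (default 5).
#' @param null_n_inner exclusion rounds per null replicate (default 5; the
#'   null has no strong pairs to exclude, so a shallow inner loop suffices).
#' @param mode `"permute"` or `"bootstrap"`.
#' @param seed RNG seed.
#' @return symmetric matrix of pseudo p-values (diagonal `NA`).
#' @export
sparcc_pseudo_p <- function(table, rho_obs, n_boot = 100, null_n_iter = 5,
                            null_n_inner = 5,
                            mode = c("permute", "bootstrap"), seed = NULL) {
  mode <- match.arg(mode)
  counts <- table_values(table)
  if (!identical(dim(rho_obs), c(nrow(counts), nrow(counts))))
    stop("rho_obs does not match the table")
  if (n_boot < 20) warning("n_boot < 20 gives a coarse pseudo p-value")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(counts)
  exceed <- matrix(0, nrow(counts), nrow(counts))
  aobs <- abs(rho_obs)
  for (b in seq_len(n_boot)) {
    null_counts <- if (mode == "permute") {
      t(apply(counts, 1, sample, size = n))
    } else {
      counts[, sample.int(n, n, replace = TRUE), drop = FALSE]
    }
    rn <- sparcc(null_counts, n_iter = null_n_iter,
                 n_inner = null_n_inner)$rho
    exceed <- exceed + (abs(rn) >= aobs - 1e-12)
  }
  pp <- (1 + exceed) / (n_boot + 1)
  diag(pp) <- NA
  dimnames(pp) <- dimnames(rho_obs)
  pp
}
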