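#' Zero-inflated Gaussian fit on CSS-log values
#'
#' Each OTU's CSS-log2 values are modelled as a mixture of a point mass at
#' zero (a technical zero, whose prior probability is a logistic function of
#' sample sequencing depth) and a Gaussian with group-specific means. An EM
#' loop alternates (i) an E-step computing the posterior probability
#' (responsibility) that each observed zero is technical and (ii) an M-step
#' of weighted least squares for the group means with weights `1 - z`, plus
#' a weighted logistic refit of the depth model. Convergence when the
#' largest parameter change drops below `tol` (default 1e-6) or after
#' `max_iter` iterations (warning, results still returned).
#'
#' @param norm a `norm_table` with method `"css_log"`.
#' @param groups two-level factor over samples (reference level first; the
#'   reported `log2_fold_change` is level 2 minus level 1).
#' @param depth_covariate per-sample log total raw counts. Defaults to the
#'   log of the CSS scale-factor-weighted totals if the table carries them.
#' @param tol,max_iter EM controls.
#' @return object of class `zig_fit`: `group_means` (OTU x 2), `s2`, `df`,
#'   responsibilities `z`, logistic coefficients `zero_model`, `groups`,
#'   `excluded` (all-zero OTUs), `converged`, `n_iter`.
#' @export
fit_zig <- function(norm, groups, depth_covariate = NULL,
                    tol = 1e-6, max_iter = 100) {
  if (!inherits(norm, "norm_table") || norm_method(norm) != "css_log")
    stop("fit_zig expects a css_log-normalized table")
  y <- unclass(norm)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  # the domestication contrast is conventionally domesticated minus wild
  if (setequal(levels(groups), c("wild", "domesticated")))
    groups <- factor(groups, levels = c("wild", "domesticated"))
  if (length(groups) != ncol(y)) stop("groups must align with samples")
  if (is.null(depth_covariate)) {
    sf <- attr(norm, "scale_factors")
    if (is.null(sf)) stop("supply depth_covariate (log total counts)")
    depth_covariate <- log(sf)
  }
  all_zero <- rowSums(y != 0) == 0
  excluded <- rownames(y)[all_zero]
  y <- y[!all_zero, , drop = FALSE]
  p <- nrow(y); n <- ncol(y)
  g2 <- groups == levels(groups)[2]
  is_zero <- y == 0
  dc <- scale(depth_covariate)[, 1]
  # init: half responsibility on zeros
  z <- matrix(0, p, n, dimnames = dimnames(y))
  z[is_zero] <- 0.5
  beta <- c(stats::qlogis(max(mean(is_zero), 1e-3)), 0)
  mu <- matrix(0, p, 2); s2 <- rep(1, p)
  converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    w <- 1 - z
    # M-step: weighted group means and residual variance per OTU
    w1 <- w[, !g2, drop = FALSE]; w2 <- w[, g2, drop = FALSE]
    y1 <- y[, !g2, drop = FALSE]; y2 <- y[, g2, drop = FALSE]
    sw1 <- rowSums(w1); sw2 <- rowSums(w2)
    mu_new <- cbind(rowSums(w1 * y1) / pmax(sw1, 1e-8),
                    rowSums(w2 * y2) / pmax(sw2, 1e-8))
    mu_mat <- mu_new[, 1] %o% as.numeric(!g2) + mu_new[, 2] %o% as.numeric(g2)
    resid <- y - mu_mat
    s2_new <- rowSums(w * resid^2) / pmax(sw1 + sw2 - 2, 1e-8)
    s2_new <- pmax(s2_new, 1e-8)
    # depth model: weighted logistic regression of technical-zero mass
    if (any(is_zero)) {
      zv <- as.vector(z); dcv <- dc[col(y)]
      fit0 <- suppressWarnings(
        stats::glm(zv ~ dcv, family = stats::quasibinomial()))
      beta_new <- stats::coef(fit0)
    } else beta_new <- c(-20, 0)
    pi_j <- stats::plogis(beta_new[1] + beta_new[2] * dc)
    # E-step: posterior technical probability for observed zeros
    z_new <- matrix(0, p, n, dimnames = dimnames(y))
    if (any(is_zero)) {
      dens <- stats::dnorm(0, mean = mu_mat,
                           sd = matrix(sqrt(s2_new), p, n))
      pim <- matrix(pi_j, p, n, byrow = TRUE)
      post <- pim / (pim + (1 - pim) * dens)
      z_new[is_zero] <- post[is_zero]
    }
    delta <- max(abs(mu_new - mu), abs(s2_new - s2), abs(z_new - z))
    mu <- mu_new; s2 <- s2_new; z <- z_new; beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  w <- 1 - z
  df <- pmax(rowSums(w) - 2, 1e-8)
  rownames(mu) <- rownames(y)
  colnames(mu) <- levels(groups)
  structure(list(group_means = mu, s2 = stats::setNames(s2, rownames(y)),
                 df = stats::setNames(df, rownames(y)), z = z,
                 zero_model = beta, groups = groups, excluded = excluded,
                 effective_n = cbind(rowSums(w[, !g2, drop = FALSE]),
                                     rowSums(w[, g2, drop = FALSE])),
                 converged = converged, n_iter = it),
            class = "zig_fit")
}

# Newton inversion of trigamma, as used for moment matching of the
# empirical-Bayes prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t statistics from a ZIG fit
#'
#' Per-OTU residual variances are shrunk towards a common prior:
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, with the prior `(d0, s0^2)`
#' estimated by moment matching of the log residual variances across OTUs
#' (equating mean and variance of `log s2` with their theoretical values
#' under a scaled inverse-chi-square prior). The moderated statistic is
#' `t = (mean2 - mean1) / (s_post * sqrt(1/n1 + 1/n2))` with effective
#' (weight-based) group sizes, referred to a t distribution on `d0 + d`
#' degrees of freedom.
#'
#' @param fit a [fit_zig()] result.
#' @param d0,s02 optional fixed prior values (estimated when `NULL`);
#'   `d0 = 0` gives the ordinary two-sample t statistic.
#' @return data.frame with `otu_id`, `log2_fold_change`, `moderated_t`,
#'   `df_total`, `p`, plus attributes `d0` and `s02`.
#' @export
moderated_t <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "zig_fit"))
  if (any(fit$effective_n < 2))
    stop("fewer than 2 effective samples in a group for some OTU")
  s2 <- fit$s2; d <- fit$df
  if (is.null(d0) || is.null(s02)) {
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ve <- stats::var(e) - mean(trigamma(d / 2))
    if (is.na(ve) || ve <= 0) {
      d0_est <- Inf
      s02_est <- exp(mean(e))
    } else {
      d0_est <- 2 * trigamma_inverse(ve)
      s02_est <- exp(mean(e) + digamma(d0_est / 2) - log(d0_est / 2))
    }
    if (is.null(d0)) d0 <- d0_est
    if (is.null(s02)) s02 <- s02_est
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  n1 <- fit$effective_n[, 1]; n2 <- fit$effective_n[, 2]
  delta <- fit$group_means[, 2] - fit$group_means[, 1]
  tt <- delta / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_tot <- pmin(d0 + d, 1e6)
  pv <- 2 * stats::pt(-abs(tt), df = df_tot)
  out <- data.frame(otu_id = names(s2), log2_fold_change = unname(delta),
                    moderated_t = unname(tt), df_total = unname(df_tot),
                    p = unname(pv), row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify OTUs by enrichment direction
#'
#' `domesticated_enriched` when `log2_fold_change > lfc_threshold` and
#' `q < q_threshold`; `wild_enriched` when `log2_fold_change <
#' -lfc_threshold` and `q < q_threshold`; otherwise `non_differential`.
#' Assumes the fold change is domesticated minus wild.
#'
#' @param records data.frame from [moderated_t()].
#' @param q q-values aligned with `records` (defaults to BH adjustment of
#'   `records$p`).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 2).
#' @param q_threshold FDR cutoff (default 0.01).
#' @return `records` with added `q` and `category` columns.
#' @export
classify_enrichment <- function(records, q = NULL, lfc_threshold = 2,
                                q_threshold = 0.01) {
  if (is.null(q)) q <- bh_fdr(records$p)
  records$q <- q
  records$category <- "non_differential"
  records$category[records$log2_fold_change > lfc_threshold &
                     q < q_threshold] <- "domesticated_enriched"
  records$category[records$log2_fold_change < -lfc_threshold &
                     q < q_threshold] <- "wild_enriched"
  records
}

#' Prevalence-based core OTU calling
#'
#' An OTU is counted present in an accession when it is detected (count > 0)
#' in at least `min_replicates` of the accession's replicates (default 1).
#' Core OTUs have prevalence (fraction of accessions where present) at or
#' above the threshold; the community convention for seed microbiota is 95%
#' for bacteria and 80% for fungi.
#'
#' @param table a [count_table()].
#' @param accession per-sample accession labels (column order or named).
#' @param prevalence_threshold fraction in (0, 1].
#' @param min_replicates detections required within an accession.
#' @return list with `otu_ids`, per-OTU `prevalence`, and the thresholds.
#' @export
core_otus <- function(table, accession, prevalence_threshold,
                      min_replicates = 1) {
  if (prevalence_threshold <= 0 || prevalence_threshold > 1)
    stop("prevalence_threshold must be in (0, 1]")
  if (!is.null(names(accession))) accession <- accession[sample_ids(table)]
  acc <- factor(accession)
  pres <- sapply(levels(acc), function(a)
    rowSums(table$counts[, acc == a, drop = FALSE] > 0) >= min_replicates)
  prevalence <- rowMeans(pres)
  list(otu_ids = otu_ids(table)[prevalence >= prevalence_threshold - 1e-12],
       prevalence = stats::setNames(prevalence, otu_ids(table)),
       threshold = prevalence_threshold, min_replicates = min_replicates)
}
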