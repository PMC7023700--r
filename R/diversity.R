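#' Alpha diversity per sample
#'
#' Computes observed OTUs, Shannon entropy (natural log), the Gini-Simpson
#' index `1 - sum(p^2)` and inverse Simpson `1 / sum(p^2)` from
#' Hellinger-transformed profiles. The Hellinger values are squared back to
#' relative shares before the indices are evaluated, so Shannon and Simpson
#' are computed on the underlying composition; the Hellinger step exists to
#' avoid rarefying depth-variable libraries.
#'
#' @param table a `norm_table` with method `"hellinger"` (see [hellinger()]).
#' @return data.frame with columns `sample_id`, `observed_otus`, `shannon`,
#'   `simpson`, `inv_simpson`.
#' @export
alpha_diversity <- function(table) {
  if (!inherits(table, "norm_table") || norm_method(table) != "hellinger")
    stop("alpha_diversity expects a hellinger-transformed table")
  p <- unclass(table)^2  # back to relative shares; columns sum to 1
  if (any(colSums(p) == 0)) stop("empty sample")
  shannon <- apply(p, 2, function(q) vegan::diversity(q, index = "shannon"))
  simpson <- apply(p, 2, function(q) vegan::diversity(q, index = "simpson"))
  inv <- apply(p, 2, function(q) vegan::diversity(q, index = "invsimpson"))
  data.frame(sample_id = colnames(p),
             observed_otus = colSums(p > 0),
             shannon = shannon, simpson = simpson, inv_simpson = inv,
             row.names = NULL)
}

#' Lorenz curve and Gini coefficient of an abundance vector
#'
#' The Lorenz curve plots the cumulative share of total abundance against
#' the cumulative fraction of OTUs ordered from lowest to highest abundance.
#' The Gini coefficient is the area between the curve and the diagonal
#' divided by the area under the diagonal, computed here in the equivalent
#' mean-absolute-difference form
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`.
#'
#' @param abundances non-negative vector with at least one positive entry.
#' @return list with `lorenz` (data.frame `p`, `L`, starting at (0,0)) and
#'   `gini`.
#' @export
lorenz_gini <- function(abundances) {
  x <- as.numeric(abundances)
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("all-zero abundance vector")
  n <- length(x)
  xs <- sort(x)
  lorenz <- data.frame(p = c(0, seq_len(n) / n),
                       L = c(0, cumsum(xs) / sum(xs)))
  # sorted-vector form of the mean absolute difference Gini
  g <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  list(lorenz = lorenz, gini = g)
}

#' Pareto fraction of an abundance vector
#'
#' Fraction `k/n` of OTUs, taken from the most abundant downwards, needed
#' for their cumulative share to first reach `target_share` of the total
#' (the "what fraction of OTUs account for 80% of reads" statistic).
#'
#' @param abundances non-negative vector with positive total.
#' @param target_share fraction in (0, 1], default 0.8.
#' @return fraction in (0, 1].
#' @export
pareto_fraction <- function(abundances, target_share = 0.8) {
  if (!is.numeric(target_share) || target_share <= 0 || target_share > 1)
    stop("target_share must be in (0, 1]")
  x <- as.numeric(abundances)
  if (sum(x) <= 0) stop("abundance total must be positive")
  cs <- cumsum(sort(x, decreasing = TRUE)) / sum(x)
  k <- which(cs >= target_share - 1e-12)[1]
  k / length(x)
}

#' Compare a per-sample statistic between groups
#'
#' Two groups: exact two-sided Wilcoxon rank-sum where no ties permit it
#' (normal approximation with tie correction otherwise). More than two
#' groups: one-way ANOVA with Tukey HSD post hoc.
#'
#' @param values numeric vector, one value per sample.
#' @param groups group labels, same length.
#' @return list with `method`, `p`, and either `wilcoxon` (htest) or
#'   `anova`/`tukey` components.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least two samples")
  if (nlevels(groups) == 2) {
    lv <- levels(groups)
    ht <- stats::wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                             alternative = "two.sided", exact = NULL)
    list(method = "wilcoxon", p = ht$p.value, wilcoxon = ht)
  } else {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    list(method = "anova", p = an[["Pr(>F)"]][1], F = an[["F value"]][1],
         anova = an, tukey = stats::TukeyHSD(fit))
  }
}
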