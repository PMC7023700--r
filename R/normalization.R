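#' Normalized OTU tables
#'
#' Normalized values are stored as an OTU-by-sample numeric matrix with a
#' `method` attribute (`"css_log"`, `"css"`, `"hellinger"`, `"relative"`) so
#' that downstream stages can enforce the normalization they expect.
#'
#' @name norm_table
NULL

new_norm_table <- function(values, method, scale_factors = NULL,
                           quantile_used = NULL, scale = NULL) {
  structure(values, class = c("norm_table", class(values)),
            method = method, scale_factors = scale_factors,
            quantile_used = quantile_used, scale = scale)
}

#' @export
print.norm_table <- function(x, ...) {
  cat("norm_table (", attr(x, "method"), "): ", nrow(x), " OTUs x ",
      ncol(x), " samples\n", sep = "")
  if (!is.null(attr(x, "quantile_used")))
    cat("  CSS quantile:", attr(x, "quantile_used"), "\n")
  invisible(x)
}

norm_method <- function(x) attr(x, "method")

table_values <- function(table) {
  if (inherits(table, "count_table")) table$counts
  else if (inherits(table, "norm_table")) unclass(table)
  else as.matrix(table)
}

#' Cumulative-sum-scaling normalization
#'
#' Per sample j, the scale factor s_j is the sum of that sample's counts
#' that are less than or equal to the chosen quantile of its positive
#' counts; normalized values are `count / s_j * scale`, optionally followed
#' by a `log2(x + 1)` transform. The quantile can be fixed or chosen
#' adaptively: with `quantile = "auto"` the smallest quantile (on a 0.05
#' grid step 0.01) at which the relative median absolute deviation of the
#' per-sample cumulative-sum fractions across samples exceeds
#' `instability_threshold` is used, falling back to 0.5 when the criterion
#' is never met.
#'
#' @param table a [count_table()].
#' @param quantile fraction in (0, 1], or `"auto"`.
#' @param log2p1 apply `log2(x + 1)` after scaling.
#' @param scale output scale constant (default 1000).
#' @param instability_threshold threshold for the adaptive quantile rule.
#' @return a `norm_table` with attributes `scale_factors` and
#'   `quantile_used`.
#' @export
css_normalize <- function(table, quantile = "auto", log2p1 = TRUE,
                          scale = 1000, instability_threshold = 0.1) {
  counts <- table_values(table)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  q <- if (identical(quantile, "auto")) {
    css_auto_quantile(counts, instability_threshold)
  } else {
    stopifnot(is.numeric(quantile), quantile > 0, quantile <= 1)
    quantile
  }
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    pos <- x[x > 0]
    qv <- stats::quantile(pos, q, names = FALSE)
    sum(x[x <= qv])
  }, numeric(1))
  if (any(sf == 0)) stop("zero CSS scale factor; quantile too low")
  vals <- sweep(counts, 2, sf, "/") * scale
  if (log2p1) vals <- log2(vals + 1)
  new_norm_table(vals, if (log2p1) "css_log" else "css",
                 scale_factors = stats::setNames(sf, colnames(counts)),
                 quantile_used = q, scale = scale)
}

# Adaptive CSS quantile: instability of relative cumulative sums across
# samples, measured as median(|r_j - median(r)|) / median(r) where
# r_j = s_j(q) / total_j.
css_auto_quantile <- function(counts, threshold = 0.1) {
  grid <- seq(0.05, 0.95, by = 0.01)
  tot <- colSums(counts)
  for (q in grid) {
    r <- vapply(seq_len(ncol(counts)), function(j) {
      x <- counts[, j]
      pos <- x[x > 0]
      qv <- stats::quantile(pos, q, names = FALSE)
      sum(x[x <= qv]) / tot[j]
    }, numeric(1))
    med <- stats::median(r)
    if (med > 0 && stats::median(abs(r - med)) / med > threshold) return(q)
  }
  0.5
}

#' Hellinger transformation
#'
#' `value = sqrt(count / sample total)`; each sample column then has unit
#' sum of squares.
#'
#' @param table a [count_table()] (or non-negative matrix).
#' @return a `norm_table` with method `"hellinger"`.
#' @export
hellinger <- function(table) {
  counts <- table_values(table)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  new_norm_table(sqrt(sweep(counts, 2, tot, "/")), "hellinger")
}

#' Relative abundance
#'
#' Columns are rescaled to sum to one.
#'
#' @inheritParams hellinger
#' @return a `norm_table` with method `"relative"`.
#' @export
relative_abundance <- function(table) {
  counts <- table_values(table)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  new_norm_table(sweep(counts, 2, tot, "/"), "relative")
}
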