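#' Pedigree of breeding lines
#'
#' A pedigree records, per cultivar, its maternal parent (or none) and a
#' breeding-line label; cultivars without any recorded connection are
#' orphans. The child-to-mother relation must be acyclic with at most one
#' recorded mother per child.
#'
#' @param edges data.frame with columns `child`, `mother`, and optionally
#'   `line`.
#' @param orphans character vector of cultivars with no recorded
#'   connections.
#' @return object of class `pedigree`.
#' @export
pedigree <- function(edges, orphans = character(0)) {
  stopifnot(all(c("child", "mother") %in% names(edges)))
  if (anyDuplicated(edges$child)) stop("a child may have at most one mother")
  if (!"line" %in% names(edges)) edges$line <- NA_character_
  cultivars <- unique(c(edges$child, edges$mother, orphans))
  mother_of <- stats::setNames(edges$mother, edges$child)
  # cycle check by chain walking
  for (c0 in names(mother_of)) {
    seen <- character(0); cur <- c0
    while (cur %in% names(mother_of)) {
      if (cur %in% seen) stop("cycle detected in pedigree at ", cur)
      seen <- c(seen, cur)
      cur <- mother_of[[cur]]
    }
  }
  line <- stats::setNames(rep(NA_character_, length(cultivars)), cultivars)
  line[edges$child] <- edges$line
  for (m in unique(edges$mother))
    if (is.na(line[m])) line[m] <- edges$line[edges$mother == m][1]
  structure(list(cultivars = cultivars, mother_of = mother_of,
                 line = line, orphans = orphans),
            class = "pedigree")
}

#' Read a pedigree TSV (child, mother, line)
#'
#' Rows with an empty/NA mother declare orphan cultivars.
#'
#' @param path TSV path.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  orphan_rows <- is.na(df$mother) | df$mother == ""
  pedigree(df[!orphan_rows, , drop = FALSE], orphans = df$child[orphan_rows])
}

maternal_ancestors <- function(ped, x) {
  out <- character(0); cur <- x
  while (cur %in% names(ped$mother_of)) {
    cur <- ped$mother_of[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Classify cultivar pairs by pedigree relationship
#'
#' `direct`: first-degree mother-progeny; `vertical`: ancestor-descendant
#' via a maternal chain of length >= 2; `kin`: at least `kin_min_shared`
#' common maternal ancestors, with neither cultivar ancestral to the other;
#' `orphan`: at least one member has no recorded connection; otherwise
#' `intra_line` (same breeding line) or `inter_line`. For `direct` and
#' `vertical` the ancestor is reported first.
#'
#' @param ped a [pedigree()].
#' @param pairs data.frame/matrix of two columns of cultivar names, or
#'   `NULL` for all unordered pairs.
#' @param kin_min_shared common maternal ancestors required for `kin`.
#' @return data.frame `cultivar_a`, `cultivar_b`, `class`.
#' @export
classify_pairs <- function(ped, pairs = NULL, kin_min_shared = 1) {
  if (is.null(pairs)) {
    cs <- sort(ped$cultivars)
    pairs <- t(utils::combn(cs, 2))
  }
  pairs <- as.matrix(pairs)
  anc <- lapply(stats::setNames(ped$cultivars, ped$cultivars),
                function(x) maternal_ancestors(ped, x))
  cls <- character(nrow(pairs))
  a_out <- pairs[, 1]; b_out <- pairs[, 2]
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!(a %in% ped$cultivars) || !(b %in% ped$cultivars))
      stop("unknown cultivar in pair: ", a, " / ", b)
    if (a %in% ped$orphans || b %in% ped$orphans) { cls[i] <- "orphan"; next }
    aa <- anc[[a]]; ab <- anc[[b]]
    if (length(ab) && ab[1] == a) {
      cls[i] <- "direct"; a_out[i] <- a; b_out[i] <- b; next
    }
    if (length(aa) && aa[1] == b) {
      cls[i] <- "direct"; a_out[i] <- b; b_out[i] <- a; next
    }
    if (a %in% ab) { cls[i] <- "vertical"; a_out[i] <- a; b_out[i] <- b; next }
    if (b %in% aa) { cls[i] <- "vertical"; a_out[i] <- b; b_out[i] <- a; next }
    if (length(intersect(aa, ab)) >= kin_min_shared) { cls[i] <- "kin"; next }
    la <- ped$line[a]; lb <- ped$line[b]
    cls[i] <- if (!is.na(la) && !is.na(lb) && la == lb) "intra_line" else "inter_line"
  }
  data.frame(cultivar_a = a_out, cultivar_b = b_out, class = cls,
             stringsAsFactors = FALSE)
}

#' Compare dissimilarities across pedigree relationship classes
#'
#' Extracts the distance of each classified pair from a cultivar-level
#' dissimilarity matrix (typically binary Bray-Curtis), summarizes each
#' class (median, IQR), and runs two-sided Wilcoxon rank-sum tests between
#' classes with BH correction. Empty classes are skipped with a note.
#'
#' @param D cultivar-level distance matrix.
#' @param classes output of [classify_pairs()].
#' @return list with `per_pair`, `summary` (per class), `tests` (pairwise
#'   Wilcoxon with `q`), `skipped`.
#' @export
compare_dissimilarity <- function(D, classes) {
  m <- as_dist_matrix(D)
  missing <- setdiff(unique(c(classes$cultivar_a, classes$cultivar_b)),
                     rownames(m))
  if (length(missing))
    stop("cultivars missing from the distance matrix: ",
         paste(missing, collapse = ", "))
  classes$distance <- m[cbind(classes$cultivar_a, classes$cultivar_b)]
  lv <- unique(classes$class)
  counts <- table(classes$class)
  skipped <- setdiff(c("direct", "vertical", "kin", "intra_line",
                       "inter_line", "orphan"), names(counts))
  summ <- do.call(rbind, lapply(lv, function(cl) {
    d <- classes$distance[classes$class == cl]
    data.frame(class = cl, n = length(d), median = stats::median(d),
               q25 = stats::quantile(d, 0.25, names = FALSE),
               q75 = stats::quantile(d, 0.75, names = FALSE))
  }))
  combs <- if (length(lv) >= 2) utils::combn(lv, 2) else NULL
  tests <- NULL
  if (!is.null(combs)) {
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      c1 <- combs[1, k]; c2 <- combs[2, k]
      d1 <- classes$distance[classes$class == c1]
      d2 <- classes$distance[classes$class == c2]
      p <- if (length(d1) >= 2 && length(d2) >= 2)
        suppressWarnings(stats::wilcox.test(d1, d2)$p.value) else NA_real_
      data.frame(class_a = c1, class_b = c2, p = p)
    }))
    tests$q <- ifelse(is.na(tests$p), NA, bh_fdr(tests$p[!is.na(tests$p)])[
      cumsum(!is.na(tests$p))])
  }
  list(per_pair = classes, summary = summ, tests = tests, skipped = skipped)
}

#' Shared and exclusive OTUs between two cultivars
#'
#' Presence = detected in at least one replicate sample of the cultivar.
#' Counts are reported per kingdom as disjoint shared / a-only / b-only
#' sets.
#'
#' @param table a [count_table()].
#' @param cultivar per-sample cultivar labels (column order or named).
#' @param a,b cultivar names.
#' @return data.frame per kingdom with `shared`, `a_only`, `b_only`.
#' @export
shared_otus <- function(table, cultivar, a, b) {
  if (!is.null(names(cultivar))) cultivar <- cultivar[sample_ids(table)]
  if (!a %in% cultivar) stop("cultivar not in table: ", a)
  if (!b %in% cultivar) stop("cultivar not in table: ", b)
  pa <- rowSums(table$counts[, cultivar == a, drop = FALSE] > 0) > 0
  pb <- rowSums(table$counts[, cultivar == b, drop = FALSE] > 0) > 0
  do.call(rbind, lapply(unique(table$kingdom), function(k) {
    kk <- table$kingdom == k
    data.frame(kingdom = k,
               shared = sum(pa & pb & kk),
               a_only = sum(pa & !pb & kk),
               b_only = sum(!pa & pb & kk))
  }))
}
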