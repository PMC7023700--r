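#' OTU count tables
#'
#' A `count_table` holds a non-negative integer OTU-by-sample matrix together
#' with a per-OTU kingdom label (`"bacteria"` or `"fungi"`) and, optionally,
#' taxonomy strings. OTUs are rows, samples are columns; this orientation is
#' the in-memory contract throughout the package and matches the on-disk TSV
#' layout.
#'
#' @param counts numeric matrix of non-negative integers with OTU ids as
#'   rownames and sample ids as colnames.
#' @param kingdom character vector, one of `"bacteria"`/`"fungi"` per OTU,
#'   either named by OTU id or in row order.
#' @param taxonomy optional character vector of lineage strings per OTU.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, kingdom, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(names(kingdom))) {
    if (!all(rownames(counts) %in% names(kingdom)))
      stop("kingdom labels missing for some OTUs")
    kingdom <- kingdom[rownames(counts)]
  }
  if (length(kingdom) != nrow(counts))
    stop("need exactly one kingdom label per OTU")
  if (!all(kingdom %in% c("bacteria", "fungi")))
    stop("kingdom labels must be 'bacteria' or 'fungi'")
  kingdom <- stats::setNames(as.character(kingdom), rownames(counts))
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) taxonomy <- taxonomy[rownames(counts)]
    if (length(taxonomy) != nrow(counts))
      stop("need one taxonomy string per OTU")
    taxonomy <- stats::setNames(as.character(taxonomy), rownames(counts))
  }
  structure(list(counts = counts, kingdom = kingdom, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples\n")
  tab <- table(x$kingdom)
  cat("  kingdoms:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  total reads:", sum(as.numeric(x$counts)), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

otu_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

# subset a count_table by OTU (i) and/or sample (j) index/name
subset_table <- function(x, i = NULL, j = NULL) {
  counts <- x$counts
  if (!is.null(i)) counts <- counts[i, , drop = FALSE]
  if (!is.null(j)) counts <- counts[, j, drop = FALSE]
  count_table(counts, x$kingdom[rownames(counts)],
              if (!is.null(x$taxonomy)) x$taxonomy[rownames(counts)])
}

#' Read an OTU table and its taxonomy annotations
#'
#' The OTU table is a TSV with a header row: first column OTU id, remaining
#' columns one per sample. The taxonomy file is a TSV with columns
#' `otu_id`, `kingdom` and optionally further lineage columns which are
#' collapsed into a single string.
#'
#' @param path path to the OTU table TSV.
#' @param taxonomy_path path to the taxonomy TSV.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, taxonomy_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("OTU table needs an id column plus at least one sample")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("OTU table cells must be non-negative integers")
  rownames(m) <- ids
  tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "kingdom") %in% names(tax)))
    stop("taxonomy file needs 'otu_id' and 'kingdom' columns")
  missing <- setdiff(ids, tax$otu_id)
  if (length(missing))
    stop("kingdom missing for OTUs: ", paste(missing, collapse = ", "))
  kingdom <- stats::setNames(tax$kingdom, tax$otu_id)[ids]
  extra <- setdiff(names(tax), c("otu_id", "kingdom"))
  taxonomy <- if (length(extra)) {
    stats::setNames(do.call(paste, c(tax[extra], sep = ";")), tax$otu_id)[ids]
  } else NULL
  count_table(m, kingdom, taxonomy)
}

#' Write an OTU table (and taxonomy) to TSV
#'
#' @param x a [count_table()].
#' @param path output path for the OTU table TSV.
#' @param taxonomy_path optional output path for the taxonomy TSV.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, taxonomy_path = NULL) {
  df <- data.frame(otu_id = otu_ids(x), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path)) {
    tax <- data.frame(otu_id = otu_ids(x), kingdom = unname(x$kingdom))
    if (!is.null(x$taxonomy)) tax$taxonomy <- unname(x$taxonomy)
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with at least `sample_id`, `accession`, `domestication_status`
#' (`wild`/`domesticated`), `genome_group`, `breeding_line`, `replicate`.
#'
#' @param path metadata TSV path.
#' @return a data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata needs a 'sample_id' column")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  if ("domestication_status" %in% names(md) &&
      !all(md$domestication_status %in% c("wild", "domesticated")))
    stop("domestication_status must be 'wild' or 'domesticated'")
  md
}

#' Drop low-abundance OTUs
#'
#' Removes OTUs whose total read count across all samples is below
#' `min_total` (strictly fewer than `min_total` reads are removed; the
#' default removes OTUs with fewer than five reads). Row order and surviving
#' counts are unchanged; the filter is idempotent.
#'
#' @param table a [count_table()].
#' @param min_total minimum total count an OTU must reach to be kept.
#' @return filtered [count_table()].
#' @export
filter_low_abundance <- function(table, min_total = 5) {
  stopifnot(min_total >= 0)
  keep <- rowSums(table$counts) >= min_total
  subset_table(table, i = which(keep))
}

#' Keep OTUs with more than a minimum number of reads
#'
#' Retains OTUs whose total count is strictly greater than `min_total`
#' (default 200), the screen used before hierarchical clustering of OTU
#' profiles.
#'
#' @inheritParams filter_low_abundance
#' @return filtered [count_table()].
#' @export
filter_min_reads <- function(table, min_total = 200) {
  stopifnot(min_total >= 0)
  keep <- rowSums(table$counts) > min_total
  if (!any(keep)) warning("no OTUs exceed ", min_total, " reads; empty table")
  subset_table(table, i = which(keep))
}

#' Remove OTUs by id (exclusion list)
#'
#' Supports removal of known contaminant / false-positive OTUs (e.g. OTUs
#' detected in negative controls, host-derived sequences) supplied as an id
#' list.
#'
#' @param table a [count_table()].
#' @param exclude character vector of OTU ids to drop.
#' @return filtered [count_table()].
#' @export
filter_exclude <- function(table, exclude) {
  subset_table(table, i = which(!otu_ids(table) %in% exclude))
}

#' Merge bacterial and fungal tables into a multi-kingdom table
#'
#' @param bact,fungi [count_table()]s over identical sample sets.
#' @return stacked [count_table()] preserving kingdom labels.
#' @export
merge_kingdoms <- function(bact, fungi) {
  if (!identical(sample_ids(bact), sample_ids(fungi)))
    stop("sample ids differ between the two tables")
  if (any(otu_ids(bact) %in% otu_ids(fungi)))
    stop("OTU ids overlap between the two tables")
  counts <- rbind(bact$counts, fungi$counts)
  taxonomy <- if (is.null(bact$taxonomy) && is.null(fungi$taxonomy)) NULL else {
    tx <- c(bact$taxonomy %||% stats::setNames(rep(NA_character_, nrow(bact$counts)), otu_ids(bact)),
            fungi$taxonomy %||% stats::setNames(rep(NA_character_, nrow(fungi$counts)), otu_ids(fungi)))
    tx
  }
  count_table(counts, c(bact$kingdom, fungi$kingdom), taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse replicate samples to accession level
#'
#' Sums counts over the replicates of each accession.
#'
#' @param table a [count_table()].
#' @param accession character vector mapping each sample (in column order or
#'   named by sample id) to its accession.
#' @return [count_table()] with one column per accession.
#' @export
collapse_replicates <- function(table, accession) {
  if (!is.null(names(accession))) accession <- accession[sample_ids(table)]
  if (length(accession) != ncol(table$counts))
    stop("need one accession per sample")
  acc <- factor(accession, levels = unique(accession))
  m <- sapply(levels(acc), function(a)
    rowSums(table$counts[, acc == a, drop = FALSE]))
  count_table(m, table$kingdom, table$taxonomy)
}
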