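#' Build a thresholded co-occurrence network
#'
#' Retains edges whose correlation magnitude strictly exceeds `r_threshold`
#' and whose pseudo p-value is below `p_threshold`. OTUs left without any
#' edge are dropped from the graph but reported in `isolated`, so the node
#' count can be smaller than the input OTU count.
#'
#' @param rho symmetric correlation matrix (OTU ids as dimnames).
#' @param pseudo_p matching pseudo p-value matrix.
#' @param kingdoms per-OTU kingdom labels (named or in row order).
#' @param r_threshold correlation magnitude cutoff (default 0.3).
#' @param p_threshold pseudo-p cutoff (default 0.05).
#' @return object of class `cooccurrence_network`: `graph` (igraph),
#'   `edges` (data.frame `from`, `to`, `rho`, `pseudo_p`, `sign`),
#'   `nodes`, `isolated`, `thresholds`.
#' @export
build_network <- function(rho, pseudo_p, kingdoms, r_threshold = 0.3,
                          p_threshold = 0.05) {
  stopifnot(identical(dim(rho), dim(pseudo_p)))
  ids <- rownames(rho)
  if (is.null(ids)) ids <- paste0("otu", seq_len(nrow(rho)))
  if (!is.null(names(kingdoms))) kingdoms <- kingdoms[ids]
  if (length(kingdoms) != nrow(rho)) stop("one kingdom label per OTU required")
  keep <- abs(rho) > r_threshold & pseudo_p < p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  keep[is.na(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = rho[idx], pseudo_p = pseudo_p[idx],
                      sign = ifelse(rho[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  connected <- unique(c(edges$from, edges$to))
  isolated <- setdiff(ids, connected)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = connected,
                          kingdom = kingdoms[match(connected, ids)]))
  structure(list(graph = g, edges = edges,
                 nodes = data.frame(otu_id = connected,
                                    kingdom = unname(kingdoms[match(connected, ids)]),
                                    stringsAsFactors = FALSE),
                 isolated = isolated,
                 thresholds = c(r = r_threshold, p = p_threshold)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|r| > ", x$thresholds["r"], ", p < ", x$thresholds["p"],
      "); ", length(x$isolated), " isolated OTUs dropped\n", sep = "")
  invisible(x)
}

#' Node centralities of a co-occurrence network
#'
#' Degree, normalized betweenness and closeness (edges treated as
#' unweighted and unsigned), and eigenvector centrality computed on the
#' largest connected component (nodes outside it get 0).
#'
#' @param net a [build_network()] result.
#' @return data.frame with `otu_id`, `kingdom`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`.
#' @export
centralities <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  cls <- suppressWarnings(igraph::closeness(g, weights = NA, normalized = TRUE))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  eig <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  ev <- igraph::eigen_centrality(sub, weights = NA)$vector
  eig[names(ev)] <- ev
  data.frame(otu_id = igraph::V(g)$name, kingdom = igraph::V(g)$kingdom,
             degree = unname(deg), betweenness = unname(btw),
             closeness = unname(cls[igraph::V(g)$name]),
             eigenvector = unname(eig),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect hub OTUs
#'
#' Hubs are nodes in the top `percentile` of both degree and betweenness
#' centrality: the cutoffs are the `1 - percentile` quantiles over nodes,
#' and hubs must strictly exceed both.
#'
#' @param net a [build_network()] result.
#' @param percentile top fraction (default 0.02).
#' @return list with `hubs`, `degree_cutoff`, `betweenness_cutoff`,
#'   `percentile`.
#' @export
detect_hubs <- function(net, percentile = 0.02) {
  cent <- centralities(net)
  dc <- stats::quantile(cent$degree, 1 - percentile, names = FALSE)
  bc <- stats::quantile(cent$betweenness, 1 - percentile, names = FALSE)
  hubs <- cent$otu_id[cent$degree > dc & cent$betweenness > bc]
  list(hubs = hubs, degree_cutoff = dc, betweenness_cutoff = bc,
       percentile = percentile)
}

#' Inter-/intra-kingdom edge proportions
#'
#' Shares of edges in the six cells {bacteria-bacteria, fungi-fungi,
#' bacteria-fungi} x {positive, negative}, summing to one.
#'
#' @param net a [build_network()] result.
#' @return named numeric vector `BB_positive`, `BB_negative`,
#'   `FF_positive`, `FF_negative`, `BF_positive`, `BF_negative`.
#' @export
kingdom_edge_proportions <- function(net) {
  e <- net$edges
  if (!nrow(e)) stop("network has no edges")
  k <- stats::setNames(net$nodes$kingdom, net$nodes$otu_id)
  if (any(is.na(k[e$from])) || any(is.na(k[e$to])))
    stop("unlabeled node in network")
  pairk <- ifelse(k[e$from] == k[e$to],
                  ifelse(k[e$from] == "bacteria", "BB", "FF"), "BF")
  cells <- paste(pairk, e$sign, sep = "_")
  lv <- c("BB_positive", "BB_negative", "FF_positive", "FF_negative",
          "BF_positive", "BF_negative")
  tab <- table(factor(cells, levels = lv))
  stats::setNames(as.numeric(tab) / nrow(e), lv)
}

#' Write network edge and node tables
#'
#' @param net a [build_network()] result.
#' @param edge_path TSV path for the edge list.
#' @param node_path optional TSV path for node centralities.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, node_path = NULL) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path))
    utils::write.table(centralities(net), node_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}
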