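#' @name topology
#' @title Per-node topology metrics: ASPL, BC, NC
#'
#' @description
#' Three shortest-path and neighborhood statistics partition a PPI network
#' into center, intermediate and peripheral regions:
#'
#' * **ASPL** (average shortest path length): mean hop distance from a node
#'   to every other node; largest at the periphery.
#' * **BC** (betweenness centrality): fraction of all-pairs shortest paths
#'   passing through a node, normalized by `(n-1)(n-2)/2` for undirected
#'   graphs so values lie in \[0, 1\] (the Cytoscape NetworkAnalyzer
#'   convention, endpoints excluded); largest at hubs.
#' * **NC** (neighborhood connectivity): mean degree of a node's neighbors;
#'   typically maximal at intermediate positions attached to hubs.
#'
#' Edges are treated as unweighted for all three metrics: confidence scores
#' gate which edges exist but are never used as path lengths.
NULL

assert_connected <- function(net, min_nodes, what) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) < min_nodes) {
    stop(what, " requires at least ", min_nodes, " nodes")
  }
  if (!igraph::is_connected(net)) {
    stop(what, " requires a connected network; ",
         "extract one with largest_connected_component() first")
  }
  invisible(TRUE)
}

#' Average shortest path length per node
#'
#' `aspl(v)` is the mean over all other nodes `u` of the hop distance
#' `d(v, u)`; the node itself (distance 0) is excluded from the average.
#'
#' @param net a connected undirected [igraph::igraph] graph with >= 2 nodes.
#' @return named numeric vector, one value >= 1 per node.
#' @export
node_aspl <- function(net) {
  assert_connected(net, 2L, "ASPL")
  d <- igraph::distances(net, weights = NA)
  rowSums(d) / (igraph::vcount(net) - 1)
}

#' Normalized betweenness centrality per node
#'
#' Freeman betweenness with all shortest paths counted and endpoints
#' excluded, divided by `(n-1)(n-2)/2` so values lie in \[0, 1\].
#'
#' @param net a connected undirected [igraph::igraph] graph with >= 3 nodes.
#' @param normalized divide by `(n-1)(n-2)/2` (default); set `FALSE` for raw
#'   path counts.
#' @return named numeric vector per node.
#' @export
node_betweenness <- function(net, normalized = TRUE) {
  assert_connected(net, 3L, "betweenness")
  igraph::betweenness(net, directed = FALSE, weights = NA,
                      normalized = normalized)
}

#' Neighborhood connectivity per node
#'
#' `nc(v)` is the mean degree of `v`'s neighbors.
#'
#' @param net an undirected [igraph::igraph] graph where every node has
#'   degree >= 1.
#' @return named numeric vector per node.
#' @export
node_neighborhood_connectivity <- function(net) {
  stopifnot(igraph::is_igraph(net))
  deg <- igraph::degree(net)
  if (any(deg == 0L)) {
    stop("neighborhood connectivity undefined for isolated node(s): ",
         paste(utils::head(names(deg)[deg == 0L], 5), collapse = ", "))
  }
  adj <- igraph::as_adj_list(net)
  out <- vapply(adj, function(nb) mean(deg[as.integer(nb)]), 1.0)
  names(out) <- igraph::V(net)$name
  out
}

#' Compute the full per-node metrics table
#'
#' @param net a connected undirected [igraph::igraph] graph with >= 3 nodes.
#' @return a data.frame with columns `node`, `degree`, `aspl`, `bc`, `nc`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, C - D, B - D)
#' node_metrics(g)
node_metrics <- function(net) {
  assert_connected(net, 3L, "node_metrics")
  data.frame(node = igraph::V(net)$name,
             degree = as.integer(igraph::degree(net)),
             aspl = unname(node_aspl(net)),
             bc = unname(node_betweenness(net)),
             nc = unname(node_neighborhood_connectivity(net)),
             stringsAsFactors = FALSE)
}

#' Write a node metrics table as TSV
#'
#' @param metrics data.frame from [node_metrics()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
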