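#' Read a confidence-scored edge table into an undirected network
#'
#' Reads a STRING-style edge list (two node columns and a numeric combined
#' score), a SIF file, or a GraphML file, rescales scores to the unit
#' interval, and keeps only edges whose confidence is strictly greater than
#' `score_threshold`. STRING protein link files report combined scores on a
#' 0--1000 integer scale; pass `score_scale = "thousand"` for those. The
#' scale is never auto-detected: the caller must declare it, and the choice
#' is logged.
#'
#' Self-loops are dropped. Duplicate undirected edges (A-B and B-A, or
#' repeated rows) are collapsed keeping the maximum score, so that an edge
#' survives the strict threshold if any of its records does.
#'
#' Node identity is the literal gene-symbol string, case-sensitive; no alias
#' mapping is attempted.
#'
#' @param path path to the edge table. Format is chosen by extension:
#'   `.sif` (SIF), `.graphml`/`.xml` (GraphML), anything else is parsed as a
#'   whitespace- or tab-delimited table with at least three columns
#'   (node1, node2, score), with or without a header line.
#' @param score_threshold edges with confidence strictly greater than this
#'   (on the unit scale) are kept. Default 0.7, the usual "high confidence"
#'   STRING cutoff.
#' @param score_scale `"unit"` if scores are already in \[0, 1\],
#'   `"thousand"` if they are STRING-style 0--1000 integers.
#' @return an undirected [igraph::igraph] graph with edge attribute
#'   `confidence` in \[0, 1\].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("a\tb\t0.9", "b\tc\t0.5"), tf)
#' g <- read_edge_table(tf, score_threshold = 0.7)
#' igraph::ecount(g)  # 1
read_edge_table <- function(path, score_threshold = 0.7,
                            score_scale = c("unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) stop("edge table not found: ", path)
  ext <- tolower(tools::file_ext(path))

  if (ext == "graphml" || ext == "xml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(confidence = "max", "ignore"))
    if (!"confidence" %in% igraph::edge_attr_names(g)) {
      stop("GraphML file lacks a 'confidence' edge attribute: ", path)
    }
    df <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(node1 = df$from, node2 = df$to,
                        score = as.numeric(df$confidence),
                        stringsAsFactors = FALSE)
  } else if (ext == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[ \t]+")
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad)) {
      stop("malformed SIF row (need node1 relation node2[ score]) at line ",
           bad[1], " of ", path)
    }
    # SIF: node1 <relation> node2 [node3 ...]; an optional numeric 4th field
    # carries the confidence, otherwise confidence defaults to 1.
    sc <- vapply(parts, function(p) {
      if (length(p) >= 4L) suppressWarnings(as.numeric(p[4])) else 1
    }, 1.0)
    edges <- data.frame(node1 = vapply(parts, `[`, "", 1L),
                        node2 = vapply(parts, `[`, "", 3L),
                        score = sc, stringsAsFactors = FALSE)
    if (anyNA(edges$score)) {
      stop("malformed SIF score at line ", which(is.na(edges$score))[1],
           " of ", path)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty edge table: ", path)
    parts <- strsplit(trimws(lines), "[ \t]+")
    first <- parts[[1]]
    has_header <- length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3])))
    row_off <- 0L
    if (has_header) {
      parts <- parts[-1]
      row_off <- 1L
      if (!length(parts)) stop("edge table has a header but no rows: ", path)
    }
    nf <- vapply(parts, length, 1L)
    if (any(nf < 3L)) {
      stop("malformed row (need node1 node2 score) at line ",
           which(nf < 3L)[1] + row_off, " of ", path)
    }
    sc <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    if (anyNA(sc)) {
      stop("non-numeric score at line ", which(is.na(sc))[1] + row_off,
           " of ", path)
    }
    edges <- data.frame(node1 = vapply(parts, `[`, "", 1L),
                        node2 = vapply(parts, `[`, "", 2L),
                        score = sc, stringsAsFactors = FALSE)
  }

  hi <- if (score_scale == "thousand") 1000 else 1
  out_of_scale <- edges$score < 0 | edges$score > hi
  if (any(out_of_scale)) {
    stop("score ", edges$score[which(out_of_scale)[1]],
         " outside declared scale [0, ", hi, "] (score_scale=\"",
         score_scale, "\")")
  }
  edges$confidence <- edges$score / hi
  nc_log("read_edge_table: ", nrow(edges), " rows from ", basename(path),
         " (score_scale=", score_scale, ")")

  # drop self-loops, collapse duplicate undirected edges keeping max score
  edges <- edges[edges$node1 != edges$node2, , drop = FALSE]
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(edges$confidence, key, max)
  uniq <- !duplicated(key)
  edges <- data.frame(node1 = a[uniq], node2 = b[uniq],
                      confidence = as.numeric(conf[key[uniq]]),
                      stringsAsFactors = FALSE)

  keep <- edges$confidence > score_threshold
  nc_log("read_edge_table: ", sum(keep), " of ", nrow(edges),
         " unique edges pass confidence > ", score_threshold)
  edges <- edges[keep, , drop = FALSE]

  g <- igraph::graph_from_data_frame(edges[, c("node1", "node2")],
                                     directed = FALSE)
  igraph::E(g)$confidence <- edges$confidence
  g
}

#' Extract the largest connected component of a network
#'
#' Topology metrics (shortest-path based) are only defined on a connected
#' graph, so the analysis runs on the largest connected component. When two
#' components tie in size, the component containing the lexicographically
#' smallest node id is chosen, making the result deterministic.
#'
#' @param net an undirected [igraph::igraph] graph.
#' @return the induced subgraph on the largest component, with an attribute
#'   `dropped_nodes` (integer count of nodes outside it).
#' @export
largest_connected_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component holding the smallest node id
    first_member <- vapply(best, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, "")
    best <- best[order(first_member)][1]
  }
  keep <- which(comp$membership == best)
  dropped <- igraph::vcount(net) - length(keep)
  if (dropped > 0L) {
    nc_log("largest_connected_component: dropped ", dropped,
           " node(s) outside the largest component")
  }
  out <- igraph::induced_subgraph(net, keep)
  attr(out, "dropped_nodes") <- dropped
  out
}

#' Join a node attribute table to the nodes of a network
#'
#' Restricts a gene-keyed attribute table (for example mean PhyloP per gene)
#' to the nodes present in the network. Nothing is imputed: network nodes
#' missing from the table and table rows missing from the network are
#' counted, logged and dropped. Duplicate gene keys are an error rather than
#' silently summarized, because how multi-row genes (isoforms) should be
#' collapsed is a scientific decision the caller must make upstream.
#'
#' @param net an [igraph::igraph] graph with named nodes.
#' @param table a data.frame whose first column (or a column named `node`)
#'   holds gene identifiers; remaining columns are attributes.
#' @return the attribute rows for genes present in the network, with counts
#'   of unmatched nodes/rows in attributes `unmatched_nodes` and
#'   `unmatched_rows`.
#' @export
join_attributes <- function(net, table) {
  stopifnot(igraph::is_igraph(net), is.data.frame(table))
  key_col <- if ("node" %in% names(table)) "node" else names(table)[1]
  keys <- as.character(table[[key_col]])
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    stop("duplicate gene keys in attribute table: ",
         paste(utils::head(dup, 10), collapse = ", "),
         if (length(dup) > 10) " ..." else "")
  }
  nodes <- igraph::V(net)$name
  matched <- keys %in% nodes
  unmatched_nodes <- sum(!(nodes %in% keys))
  unmatched_rows <- sum(!matched)
  nc_log("join_attributes: ", sum(matched), " matched; ",
         unmatched_nodes, " network node(s) without attributes; ",
         unmatched_rows, " attribute row(s) not in network")
  out <- table[matched, , drop = FALSE]
  names(out)[names(out) == key_col] <- "node"
  out$node <- as.character(out$node)
  rownames(out) <- NULL
  attr(out, "unmatched_nodes") <- unmatched_nodes
  attr(out, "unmatched_rows") <- unmatched_rows
  out
}

#' Write a network as a tab-delimited edge list or GraphML
#'
#' @param net an [igraph::igraph] graph with a `confidence` edge attribute.
#' @param path output path; `.graphml` extension selects GraphML, anything
#'   else a three-column TSV (node1, node2, confidence) with header.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  if (tolower(tools::file_ext(path)) == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(net, what = "edges")
    conf <- if ("confidence" %in% names(df)) df$confidence else 1
    con <- file(path, open = "wb")  # binary mode forces LF endings
    on.exit(close(con))
    writeLines(c("node1\tnode2\tcombined_score",
                 sprintf("%s\t%s\t%s", df$from, df$to, format(conf))), con)
  }
  invisible(path)
}
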