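# Brute-force graph-metric oracles, independent of igraph's algorithms.
# Graphs are two-column character edge matrices; the oracles work on a
# plain adjacency list and enumerate shortest paths explicitly.

options(netconstraint.quiet = TRUE)

edges_to_adj <- function(edges) {
  nodes <- sort(unique(as.character(edges)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

edges_to_graph <- function(edges) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  igraph::E(g)$confidence <- 1
  g
}

# single-source BFS hop distances
oracle_bfs <- function(adj, source) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_aspl <- function(edges) {
  adj <- edges_to_adj(edges)
  vapply(names(adj), function(v) {
    d <- oracle_bfs(adj, v)
    mean(d[names(d) != v])
  }, 1.0)
}

oracle_nc <- function(edges) {
  adj <- edges_to_adj(edges)
  deg <- vapply(adj, length, 1L)
  vapply(names(adj), function(v) mean(deg[adj[[v]]]), 1.0)
}

# enumerate every shortest s-t path as a node sequence
enumerate_shortest_paths <- function(adj, dist_to_t, s, t) {
  if (s == t) return(list(s))
  out <- list()
  for (u in adj[[s]]) {
    if (dist_to_t[u] == dist_to_t[s] - 1) {
      for (p in enumerate_shortest_paths(adj, dist_to_t, u, t)) {
        out[[length(out) + 1L]] <- c(s, p)
      }
    }
  }
  out
}

oracle_bc <- function(edges, normalized = TRUE) {
  adj <- edges_to_adj(edges)
  nodes <- names(adj)
  n <- length(nodes)
  bc <- stats::setNames(rep(0, n), nodes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- nodes[i]; t <- nodes[j]
      dist_to_t <- oracle_bfs(adj, t)
      paths <- enumerate_shortest_paths(adj, dist_to_t, s, t)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# fixture suite of small connected graphs (<= 10 nodes)
path_edges <- function(n) {
  v <- sprintf("n%02d", seq_len(n))
  cbind(v[-n], v[-1])
}
cycle_edges <- function(n) {
  v <- sprintf("n%02d", seq_len(n))
  rbind(cbind(v[-n], v[-1]), c(v[n], v[1]))
}
star_edges <- function(k) cbind("c", sprintf("l%02d", seq_len(k)))
complete_edges <- function(n) t(utils::combn(sprintf("n%02d", seq_len(n)), 2))

random_connected_edges <- function(n, p, seed) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::vcount(g) == n) break
    seed <- seed + 1
  }
  el <- igraph::as_edgelist(g)
  matrix(sprintf("n%02d", el), ncol = 2)
}

fixture_graphs <- function() {
  set.seed(20240216)
  fx <- list(path3 = path_edges(3), path5 = path_edges(5),
             cycle5 = cycle_edges(5), cycle8 = cycle_edges(8),
             star4 = star_edges(4), star7 = star_edges(7),
             k4 = complete_edges(4), k6 = complete_edges(6),
             barbell = rbind(complete_edges(3),
                             c("n01", "b1"), c("b1", "m01"),
                             matrix(c("m01", "m02", "m02", "m03",
                                      "m03", "m01"), ncol = 2, byrow = TRUE)))
  for (i in 1:6) {
    fx[[paste0("gnp", i)]] <- random_connected_edges(6 + i %% 5, 0.35, i)
  }
  fx
}

# well-separated three-class metrics fixture for classifier tests
separable_metrics <- function(n_per = 20L, seed = 1L, sd = 0.05) {
  set.seed(seed)
  mk <- function(cls, n, aspl, bc, nc) {
    data.frame(node = sprintf("%s%03d", cls, seq_len(n)),
               degree = 3L,
               aspl = stats::rnorm(n, aspl, sd * aspl),
               bc = pmax(0, stats::rnorm(n, bc, sd * bc)),
               nc = stats::rnorm(n, nc, sd * nc),
               stringsAsFactors = FALSE)
  }
  metrics <- rbind(mk("H", n_per, 2, 0.60, 8),
                   mk("I", n_per, 4, 0.05, 20),
                   mk("P", n_per, 8, 0.001, 2))
  labels <- factor(rep(c("H", "I", "P"), each = n_per),
                   levels = c("H", "I", "P"))
  list(metrics = metrics,
       seeds = data.frame(node = metrics$node, label = labels,
                          stringsAsFactors = FALSE))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
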