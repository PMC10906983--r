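#' Specification for a synthetic constraint-network study
#'
#' Bundles all parameters of the synthetic generator: a three-layer network
#' architecture (a dense hub core, an intermediate shell wired to the core,
#' and tree-like peripheral fringes), a planted center-to-periphery
#' constraint gradient, and a focal gene set concentrated in intermediate
#' nodes with a rate-direction effect.
#'
#' Defaults give a 255-node network (5 hubs, 50 intermediate, 200
#' peripheral) and an 18-gene focal set split 10 accelerated / 8
#' decelerated, mirroring the scale of a hibernation-associated gene set;
#' the constraint gradient means decrease from hubs to periphery
#' (`mu = c(H = 1.2, I = 0.8, P = 0.4)` on the gene-level mean-PhyloP
#' scale) with Gaussian noise `sd = 0.25`, and accelerated focal genes sit
#' `direction_effect = 0.3` above their class mean.
#'
#' @param n_hub,n_intermediate,n_peripheral layer sizes.
#' @param hub_links_per_intermediate hub attachments per intermediate node
#'   (preferential by current hub degree, giving a heavy-tailed hub degree
#'   distribution).
#' @param intra_shell_p probability an intermediate node also links to an
#'   earlier intermediate node.
#' @param chain_p probability a peripheral node extends an existing
#'   peripheral chain rather than starting a new one at an intermediate
#'   node.
#' @param mu named numeric: planted mean constraint per class, must
#'   decrease H > I > P.
#' @param sd Gaussian noise SD on the constraint scale.
#' @param radial_decline within-class decline in mean constraint per hop of
#'   distance from the hub core, centered so class means stay at `mu`; this
#'   makes the planted gradient genuinely radial (constraint declines
#'   gradually along peripheral chains) rather than a three-level step.
#' @param focal_size number of focal genes.
#' @param focal_intermediate_fraction fraction of focal genes drawn from
#'   planted-intermediate nodes; the remainder come from peripheral nodes.
#' @param n_accelerated,n_decelerated direction split of the focal set
#'   (must sum to `focal_size`).
#' @param direction_effect constraint offset added to accelerated focal
#'   genes.
#' @param seed integer seed; the whole instance is deterministic in it.
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_hub = 5L, n_intermediate = 50L,
                           n_peripheral = 200L,
                           hub_links_per_intermediate = 2L,
                           intra_shell_p = 0.1, chain_p = 0.6,
                           mu = c(H = 1.2, I = 0.8, P = 0.4), sd = 0.25,
                           radial_decline = 0.1,
                           focal_size = 18L,
                           focal_intermediate_fraction = 14 / 18,
                           n_accelerated = 10L, n_decelerated = 8L,
                           direction_effect = 0.3, seed = 1L) {
  spec <- list(n_hub = as.integer(n_hub),
               n_intermediate = as.integer(n_intermediate),
               n_peripheral = as.integer(n_peripheral),
               hub_links_per_intermediate = as.integer(hub_links_per_intermediate),
               intra_shell_p = intra_shell_p, chain_p = chain_p,
               mu = mu, sd = sd, radial_decline = radial_decline,
               focal_size = as.integer(focal_size),
               focal_intermediate_fraction = focal_intermediate_fraction,
               n_accelerated = as.integer(n_accelerated),
               n_decelerated = as.integer(n_decelerated),
               direction_effect = direction_effect, seed = as.integer(seed))
  if (spec$n_hub < 3L) stop("need at least 3 hub nodes (core clique)")
  if (spec$n_intermediate < 5L || spec$n_peripheral < 5L) {
    stop("intermediate and peripheral layers need at least 5 nodes each")
  }
  if (spec$hub_links_per_intermediate > spec$n_hub) {
    stop("hub_links_per_intermediate cannot exceed n_hub")
  }
  if (!all(c("H", "I", "P") %in% names(mu)) ||
      !(mu["H"] > mu["I"] && mu["I"] > mu["P"])) {
    stop("planted means must satisfy mu[H] > mu[I] > mu[P]")
  }
  if (sd < 0) stop("sd must be non-negative")
  if (radial_decline < 0) stop("radial_decline must be non-negative")
  if (spec$n_accelerated + spec$n_decelerated != spec$focal_size) {
    stop("n_accelerated + n_decelerated must equal focal_size")
  }
  if (spec$focal_intermediate_fraction < 0 ||
      spec$focal_intermediate_fraction > 1) {
    stop("focal_intermediate_fraction must be in [0, 1]")
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic three-layer network with planted classes
#'
#' Builds a connected undirected graph with the architecture the topology
#' metrics are meant to resolve: a hub core (clique) carrying the highest
#' betweenness, an intermediate shell attached preferentially to the core
#' (so its neighbors are high-degree and its neighborhood connectivity is
#' the highest), and peripheral chains hanging off the shell (highest
#' average shortest path length). All edges carry confidence 1.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (igraph) and `truth` (data.frame `node`,
#'   `class` in H/I/P).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_total <- spec$n_hub + spec$n_intermediate + spec$n_peripheral
  ids <- sprintf("G%04d", seq_len(n_total))
  hub_ids <- ids[seq_len(spec$n_hub)]
  int_ids <- ids[spec$n_hub + seq_len(spec$n_intermediate)]
  per_ids <- ids[spec$n_hub + spec$n_intermediate +
                   seq_len(spec$n_peripheral)]

  edges <- with_seed(derive_seed(spec$seed, "network"), {
    e <- list()
    # hub core: clique
    core <- t(utils::combn(hub_ids, 2L))
    e[[length(e) + 1L]] <- core
    hub_deg <- stats::setNames(rep(spec$n_hub - 1, spec$n_hub), hub_ids)
    # intermediate shell: preferential attachment to hubs
    for (v in int_ids) {
      targets <- sample(hub_ids, spec$hub_links_per_intermediate,
                        prob = hub_deg[hub_ids])
      hub_deg[targets] <- hub_deg[targets] + 1
      e[[length(e) + 1L]] <- cbind(v, targets)
      prev <- int_ids[seq_len(match(v, int_ids) - 1L)]
      if (length(prev) && stats::runif(1) < spec$intra_shell_p) {
        e[[length(e) + 1L]] <- cbind(v, sample(prev, 1L))
      }
    }
    # peripheral fringes: chains rooted at intermediate nodes, grown only
    # at their tips so no peripheral node ever accumulates a subtree large
    # enough to rival hub betweenness
    tips <- character(0)
    for (v in per_ids) {
      extend <- length(tips) > 0 && stats::runif(1) < spec$chain_p
      if (extend) {
        tip <- sample(seq_along(tips), 1L)
        e[[length(e) + 1L]] <- cbind(v, tips[tip])
        tips[tip] <- v
      } else {
        e[[length(e) + 1L]] <- cbind(v, sample(int_ids, 1L))
        tips <- c(tips, v)
      }
    }
    do.call(rbind, e)
  })

  g <- igraph::graph_from_edgelist(unname(edges), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::E(g)$confidence <- 1
  truth <- data.frame(node = c(hub_ids, int_ids, per_ids),
                      class = rep(c("H", "I", "P"),
                                  c(spec$n_hub, spec$n_intermediate,
                                    spec$n_peripheral)),
                      stringsAsFactors = FALSE)
  # hop distance from the hub core, the axis of the planted radial gradient
  d_core <- igraph::distances(g, to = hub_ids, weights = NA)
  truth$core_distance <- apply(d_core, 1, min)[truth$node]
  list(network = g, truth = truth)
}

#' Sample a focal gene set planted in intermediate positions
#'
#' Draws `focal_size` genes, a fixed fraction from planted-intermediate
#' nodes and the remainder from peripheral nodes, and assigns rate
#' directions (accelerated vs decelerated) at random with the spec's split
#' (default 10 accelerated / 8 decelerated).
#'
#' @param truth ground-truth table from [generate_network()].
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `node`, `direction`.
#' @export
generate_focal_set <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            all(c("node", "class") %in% names(truth)))
  n_int <- round(spec$focal_size * spec$focal_intermediate_fraction)
  n_per <- spec$focal_size - n_int
  pool_i <- truth$node[truth$class == "I"]
  pool_p <- truth$node[truth$class == "P"]
  if (n_int > length(pool_i) || n_per > length(pool_p)) {
    stop("focal_intermediate_fraction infeasible for these layer sizes")
  }
  with_seed(derive_seed(spec$seed, "focal"), {
    genes <- c(sample(pool_i, n_int), sample(pool_p, n_per))
    direction <- sample(rep(c("accelerated", "decelerated"),
                            c(spec$n_accelerated, spec$n_decelerated)))
    data.frame(node = genes, direction = direction, stringsAsFactors = FALSE)
  })
}

#' Generate per-gene constraint values with a planted gradient
#'
#' Draws gene-level mean PhyloP from `Normal(mu[class] + r, sd)` where `r`
#' is a within-class radial term, `-radial_decline` per hop of distance
#' from the hub core centered within each class (so class means stay at
#' `mu[class]` while constraint still declines gradually along peripheral
#' chains). Accelerated focal genes are shifted up by `direction_effect`
#' (faster-evolving focal genes carry higher constraint).
#'
#' @param truth ground-truth table from [generate_network()].
#' @param spec a [synthetic_spec()].
#' @param focal optional focal set from [generate_focal_set()]; when given,
#'   its accelerated genes receive the direction offset.
#' @return data.frame with columns `node`, `mean_phylop`.
#' @export
generate_constraint <- function(truth, spec, focal = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  radial <- if (!is.null(truth$core_distance)) {
    centered <- truth$core_distance -
      stats::ave(truth$core_distance, truth$class)
    -spec$radial_decline * centered
  } else 0
  vals <- with_seed(derive_seed(spec$seed, "constraint"), {
    stats::rnorm(nrow(truth), spec$mu[truth$class] + radial, spec$sd)
  })
  if (!is.null(focal)) {
    acc <- focal$node[focal$direction == "accelerated"]
    vals[truth$node %in% acc] <- vals[truth$node %in% acc] +
      spec$direction_effect
  }
  data.frame(node = truth$node, mean_phylop = vals, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study instance
#'
#' Runs [generate_network()], [generate_focal_set()] and
#' [generate_constraint()] in order and returns all pieces.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network`, `truth`, `focal`, `attributes`, `spec`.
#' @export
#' @examples
#' study <- simulate_study(synthetic_spec(seed = 42))
#' igraph::vcount(study$network)  # 255
simulate_study <- function(spec = synthetic_spec()) {
  net <- generate_network(spec)
  focal <- generate_focal_set(net$truth, spec)
  attributes <- generate_constraint(net$truth, spec, focal = focal)
  list(network = net$network, truth = net$truth, focal = focal,
       attributes = attributes, spec = spec)
}
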