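#' Generate a random spatial multi-layer network
#'
#' Builds the spatial substrate of the simulation: nodes placed uniformly at
#' random in the unit square, connected by a random-geometric rule (all pairs
#' within a radius chosen to hit a target mean degree), then augmented with
#' minimum-spanning-tree edges so the union graph is always connected. A random
#' subset of \code{floor(food_frac * n_nodes)} nodes is labelled a food
#' producer; the rest produce mostly non-food goods. The same undirected
#' topology is used for all three layers (population, food, non-food) unless
#' per-layer edge masks are supplied; flows on the links are directed.
#'
#' @param n_nodes number of location nodes (>= 2).
#' @param food_frac fraction of nodes that are food producers, strictly
#'   between 0 and 1.
#' @param target_mean_degree desired mean degree of the geometric graph
#'   (>= 2). The connection radius is the k-th smallest pairwise distance with
#'   k = round(n_nodes * target_mean_degree / 2), so the pre-augmentation mean
#'   degree hits the target up to rounding.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param layer_masks optional named list with logical vectors (one entry per
#'   generated edge) for any of \code{"population"}, \code{"food"},
#'   \code{"nonfood"}, keeping only a subset of edges on that layer.
#' @return An object of class \code{cascade_network}: a list with
#'   \code{nodes}, \code{coords} (n x 2), \code{dist} (n x n Euclidean),
#'   \code{edges} (two-column matrix of undirected links),
#'   \code{layers} (named list of edge index vectors),
#'   \code{producer_type} (factor, \code{"food"}/\code{"nonfood"}),
#'   \code{degree} (per-layer and union counts) and the generating call's
#'   parameters.
#' @examples
#' net <- generate_network(20, food_frac = 0.5, target_mean_degree = 4, seed = 1)
#' table(net$producer_type)
#' @export
generate_network <- function(n_nodes, food_frac = 0.5, target_mean_degree = 8,
                             seed = 1L, layer_masks = NULL) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop("configuration error: 'n_nodes' must be a single number >= 2")
  if (!is.numeric(food_frac) || food_frac <= 0 || food_frac >= 1)
    stop("configuration error: 'food_frac' must lie strictly between 0 and 1")
  if (!is.numeric(target_mean_degree) || target_mean_degree < 2)
    stop("configuration error: 'target_mean_degree' must be >= 2")
  n <- as.integer(n_nodes)

  set.seed(as.integer(seed))
  coords <- cbind(x = stats::runif(n), y = stats::runif(n))
  d <- as.matrix(stats::dist(coords))

  ## radius = k-th smallest pairwise distance so that the geometric graph has
  ## ~ n * target_mean_degree / 2 edges
  dv <- d[upper.tri(d)]
  k <- max(1L, min(length(dv), as.integer(round(n * target_mean_degree / 2))))
  r <- sort(dv)[k]
  idx <- which(upper.tri(d) & d <= r, arr.ind = TRUE)
  edges <- cbind(u = idx[, 1L], v = idx[, 2L])

  ## force connectivity through MST edges of the complete distance graph
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE)
  mst <- igraph::mst(g_full)
  me <- igraph::as_edgelist(mst, names = FALSE)
  me <- cbind(u = pmin(me[, 1L], me[, 2L]), v = pmax(me[, 1L], me[, 2L]))
  key <- function(m) paste(m[, 1L], m[, 2L])
  add <- me[!(key(me) %in% key(edges)), , drop = FALSE]
  edges <- rbind(edges, add)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  n_food <- floor(food_frac * n)
  if (n_food < 1L || n_food >= n)
    stop("configuration error: 'food_frac' leaves no producers of one type")
  ptype <- rep("nonfood", n)
  ptype[sample.int(n, n_food)] <- "food"

  layers <- list(population = seq_len(nrow(edges)),
                 food = seq_len(nrow(edges)),
                 nonfood = seq_len(nrow(edges)))
  if (!is.null(layer_masks)) {
    for (nm in names(layer_masks)) {
      if (!nm %in% names(layers))
        stop("configuration error: unknown layer '", nm, "'")
      layers[[nm]] <- which(as.logical(layer_masks[[nm]]))
    }
  }

  net <- structure(list(
    nodes = seq_len(n),
    coords = coords,
    dist = d,
    edges = edges,
    layers = layers,
    producer_type = factor(ptype, levels = c("food", "nonfood")),
    degree = network_degrees(edges, layers, n),
    params = list(n_nodes = n, food_frac = food_frac,
                  target_mean_degree = target_mean_degree, seed = seed,
                  radius = r)
  ), class = "cascade_network")
  stopifnot(network_connected(net))
  net
}

network_degrees <- function(edges, layers, n) {
  deg_of <- function(ix) {
    e <- edges[ix, , drop = FALSE]
    tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  }
  out <- lapply(layers, deg_of)
  out$union <- deg_of(sort(unique(unlist(layers))))
  out
}

network_connected <- function(net) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(net$nodes) - igraph::vcount(g)))
  igraph::is_connected(g)
}

#' @export
print.cascade_network <- function(x, ...) {
  cat("Multi-layer cascade network\n")
  cat(sprintf("  nodes: %d (%d food, %d non-food)\n", length(x$nodes),
              sum(x$producer_type == "food"), sum(x$producer_type == "nonfood")))
  cat(sprintf("  undirected links: %d (mean union degree %.2f)\n",
              nrow(x$edges), mean(x$degree$union)))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Neighbors of a node in the union graph
#'
#' @param net a \code{cascade_network}.
#' @param i node id.
#' @param layer layer name, or \code{"union"} (default) for the union of all
#'   three link sets.
#' @return integer vector of neighboring node ids.
#' @export
neighbors_of <- function(net, i, layer = "union") {
  ix <- if (identical(layer, "union")) sort(unique(unlist(net$layers)))
        else net$layers[[layer]]
  e <- net$edges[ix, , drop = FALSE]
  sort(unique(c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L])))
}

#' Select the epicenter region of the disaster
#'
#' Returns all nodes within Euclidean \code{radius} of \code{center}. The
#' output shock is later applied only to the food-producing members of this
#' set, so a region with no food producers is rejected as a scenario error.
#'
#' @param net a \code{cascade_network}.
#' @param center numeric length-2 (x, y) in the unit square.
#' @param radius positive radius in unit-square units.
#' @return integer vector of node ids inside the region, with the food-node
#'   subset in attribute \code{"food_nodes"} and the center in \code{"center"}.
#' @examples
#' net <- generate_network(20, seed = 1)
#' ep <- select_epicenter(net, center = c(0.25, 0.25),
#'                        radius = epicenter_radius(net, frac = 0.3))
#' @export
select_epicenter <- function(net, center = c(0.25, 0.25), radius) {
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be positive")
  dd <- sqrt((net$coords[, 1L] - center[1L])^2 +
             (net$coords[, 2L] - center[2L])^2)
  ids <- which(dd <= radius)
  if (length(ids) == 0L)
    stop("scenario error: epicenter contains no nodes")
  food <- ids[net$producer_type[ids] == "food"]
  if (length(food) == 0L)
    stop("scenario error: epicenter contains no food-producing nodes; ",
         "the shock would be a no-op")
  structure(ids, food_nodes = food, center = center, radius = radius)
}

#' Radius holding a given fraction of nodes around a center
#'
#' Convenience for sizing the epicenter: the distance from \code{center} to
#' its \code{ceiling(frac * n)}-th nearest node.
#'
#' @inheritParams select_epicenter
#' @param frac fraction of nodes the region should hold (default 0.2).
#' @return a radius usable with \code{\link{select_epicenter}}.
#' @export
epicenter_radius <- function(net, center = c(0.25, 0.25), frac = 0.2) {
  stopifnot(frac > 0, frac <= 1)
  dd <- sqrt((net$coords[, 1L] - center[1L])^2 +
             (net$coords[, 2L] - center[2L])^2)
  sort(dd)[ceiling(frac * length(dd))]
}

#' Normalized distances from a node to its neighbors
#'
#' Distances enter the diffusion rules as fractions of the farthest connected
#' neighbor's distance, so the farthest neighbor maps to exactly 1 and the
#' penalty is invariant to rescaling all coordinates.
#'
#' @param net a \code{cascade_network}.
#' @param i node id with at least one neighbor.
#' @param layer layer for the neighborhood (default union graph).
#' @return named numeric vector of d_ij / max_j d_ij over i's neighbors.
#' @export
normalized_distances <- function(net, i, layer = "union") {
  nb <- neighbors_of(net, i, layer)
  if (length(nb) == 0L)
    stop("node ", i, " is isolated; cannot normalize over an empty set")
  d <- net$dist[i, nb]
  stats::setNames(d / max(d), nb)
}

#' Export / import a network as plain-text tables
#'
#' Writes (reads) a node table \code{(id, x, y, producer_type)} and an edge
#' table \code{(layer, u, v, distance)} as tab-separated files, the exchange
#' format for user-supplied networks.
#'
#' @param net a \code{cascade_network}.
#' @param node_file,edge_file file paths.
#' @return \code{write_network} invisibly returns \code{net};
#'   \code{read_network} returns a \code{cascade_network}.
#' @export
write_network <- function(net, node_file, edge_file) {
  nodes <- data.frame(id = net$nodes, x = net$coords[, 1L],
                      y = net$coords[, 2L],
                      producer_type = as.character(net$producer_type))
  ed <- do.call(rbind, lapply(names(net$layers), function(ly) {
    e <- net$edges[net$layers[[ly]], , drop = FALSE]
    data.frame(layer = ly, u = e[, 1L], v = e[, 2L],
               distance = net$dist[cbind(e[, 1L], e[, 2L])])
  }))
  utils::write.table(nodes, node_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(ed, edge_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(net)
}

#' @rdname write_network
#' @export
read_network <- function(node_file, edge_file) {
  nodes <- utils::read.table(node_file, header = TRUE, sep = "\t")
  ed <- utils::read.table(edge_file, header = TRUE, sep = "\t")
  n <- nrow(nodes)
  coords <- cbind(x = nodes$x, y = nodes$y)
  d <- as.matrix(stats::dist(coords))
  uedges <- unique(ed[, c("u", "v")])
  uedges <- cbind(u = pmin(uedges$u, uedges$v), v = pmax(uedges$u, uedges$v))
  uedges <- unique(uedges)
  uedges <- uedges[order(uedges[, 1L], uedges[, 2L]), , drop = FALSE]
  ekey <- paste(uedges[, 1L], uedges[, 2L])
  layers <- lapply(split(ed, ed$layer), function(s)
    match(paste(pmin(s$u, s$v), pmax(s$u, s$v)), ekey))
  layers <- layers[c("population", "food", "nonfood")]
  structure(list(
    nodes = nodes$id, coords = coords, dist = d, edges = uedges,
    layers = layers,
    producer_type = factor(nodes$producer_type, levels = c("food", "nonfood")),
    degree = network_degrees(uedges, layers, n),
    params = list(n_nodes = n, source = "file")
  ), class = "cascade_network")
}
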