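#' Build a multi-layer network from explicit tables
#'
#' Constructs a \code{cascade_network} from user-supplied coordinates, an
#' undirected edge list and producer types — the entry point for hand-built
#' fixtures and externally defined networks.
#'
#' @param coords n x 2 matrix of (x, y) positions.
#' @param edges two-column matrix of undirected links (node ids).
#' @param producer_type character vector, \code{"food"} / \code{"nonfood"}.
#' @param layer_masks optional per-layer logical edge masks (see
#'   \code{\link{generate_network}}).
#' @return a \code{cascade_network}.
#' @export
manual_network <- function(coords, edges, producer_type, layer_masks = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(producer_type) == n, ncol(coords) == 2L)
  edges <- cbind(u = pmin(edges[, 1L], edges[, 2L]),
                 v = pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (any(edges[, 1L] == edges[, 2L])) stop("self-links are not allowed")
  layers <- list(population = seq_len(nrow(edges)),
                 food = seq_len(nrow(edges)),
                 nonfood = seq_len(nrow(edges)))
  if (!is.null(layer_masks))
    for (nm in names(layer_masks)) layers[[nm]] <- which(layer_masks[[nm]])
  structure(list(
    nodes = seq_len(n), coords = coords, dist = as.matrix(stats::dist(coords)),
    edges = edges, layers = layers,
    producer_type = factor(producer_type, levels = c("food", "nonfood")),
    degree = network_degrees(edges, layers, n),
    params = list(n_nodes = n, source = "manual")
  ), class = "cascade_network")
}

#' Two-node fixture: one food and one non-food producer
#'
#' The smallest system exercising the full interaction loop: one link, a
#' configurable initial wage gap (created by unequal labor endowments), and a
#' closed-form convergence target — equal real wages, which with symmetric
#' producers means labor splits equally, so each node ends with the mean of
#' the initial stocks (total labor is conserved).
#'
#' @param wage_gap relative initial wage gap >= 0: node 1 starts with
#'   \code{L0 * (1 + wage_gap)} workers (hence the lower wage).
#' @param scenario base \code{cascade_scenario} supplying the economy and
#'   diffusion parameters.
#' @return list of class \code{cascade_fixture}: \code{name}, \code{net},
#'   \code{scenario}, \code{state} (initial state for
#'   \code{\link{cascade_tick}}) and \code{expected} values with provenance.
#' @export
two_node_fixture <- function(wage_gap = 0.5, scenario = cascade_scenario()) {
  stopifnot(wage_gap >= 0)
  net <- manual_network(rbind(c(0.25, 0.5), c(0.75, 0.5)),
                        rbind(c(1L, 2L)), c("food", "nonfood"))
  ec <- scenario$economy
  L <- c(ec$L0 * (1 + wage_gap), ec$L0)
  x_F <- c(ec$x_food[1L], ec$x_nonfood[1L])
  x_G <- c(ec$x_food[2L], ec$x_nonfood[2L])
  y <- real_output(x_F, x_G, c(ec$beta_food[1L], ec$beta_food[2L]),
                   c(ec$beta_food[2L], ec$beta_food[1L]))
  w <- wage_rate(y, L, ec$rho)
  pr <- node_prices(ec$alpha0, w, L, x_F, x_G)
  state <- list(L = L, x_F = x_F, x_G = x_G,
                alpha = rep(ec$alpha0, 2L), w = w,
                p_F = pr$p_F, p_G = pr$p_G,
                p = price_index(pr$p_F, pr$p_G, ec$gamma_F, ec$gamma_G))
  structure(list(
    name = "two_node", net = net, scenario = scenario, state = state,
    expected = list(
      total_labor = list(value = sum(L),
                         provenance = "trivial: conservation"),
      L_final = list(value = rep(mean(L), 2L),
                     provenance = paste("derived: equal real wages +",
                                        "symmetric producers + conservation")),
      zero_flow_if_no_gap = list(value = wage_gap == 0,
                                 provenance = "trivial: symmetric fixed point")
    )), class = "cascade_fixture")
}

#' Star fixture: a hub with n identical leaves
#'
#' Exercises share normalization across many neighbors: identical leaves must
#' receive equal shares 1/n of anything the hub diffuses.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param scenario base \code{cascade_scenario}.
#' @return a \code{cascade_fixture} (hub is node 1, a food producer; leaves
#'   are non-food producers placed symmetrically around it).
#' @export
star_fixture <- function(n_leaves = 4L, scenario = cascade_scenario()) {
  stopifnot(n_leaves >= 2L)
  th <- 2 * pi * seq_len(n_leaves) / n_leaves
  coords <- rbind(c(0.5, 0.5), cbind(0.5 + 0.3 * cos(th), 0.5 + 0.3 * sin(th)))
  edges <- cbind(rep(1L, n_leaves), seq_len(n_leaves) + 1L)
  net <- manual_network(coords, edges, c("food", rep("nonfood", n_leaves)))
  structure(list(
    name = "star", net = net, scenario = scenario, state = NULL,
    expected = list(
      equal_shares = list(value = rep(1 / n_leaves, n_leaves),
                          provenance = "trivial: identical leaves"))),
    class = "cascade_fixture")
}

#' @export
print.cascade_fixture <- function(x, ...) {
  cat(sprintf("Cascade fixture '%s': %d nodes, %d links\n", x$name,
              length(x$net$nodes), nrow(x$net$edges)))
  invisible(x)
}
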