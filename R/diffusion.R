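#' Gravity-model diffusion primitives
#'
#' Trade and migration flows follow a gravity logic: the propensity to move
#' goods or workers to a connected neighbor rises with the relative economic
#' gain there and falls with distance. Gains map onto probabilities through a
#' generic logistic curve, distance enters as a normalized fraction with the
#' probabilities reversed (nearest ~ 1), and the per-neighbor probabilities
#' are normalized into shares of the quantity diffused.
#'
#' @name diffusion
NULL

#' Generic logistic probability
#'
#' Pi(z) = 1 / (a + b * exp(-z)). With the defaults a = b = 1 this is the
#' standard logistic: 0.5 at z = 0, approaching 1/a for large gains and 0 for
#' large losses.
#'
#' @param z dimensionless gain argument.
#' @param a,b positive curve parameters.
#' @return probability value(s).
#' @examples
#' logistic_prob(0)   # 0.5
#' logistic_prob(2)   # ~0.8808
#' @export
logistic_prob <- function(z, a = 1, b = 1) {
  stopifnot(a > 0, b > 0)
  1 / (a + b * exp(-z))
}

#' Joint gain-distance probability
#'
#' Pi_ij = Pi_q * (1 - Pi_d): the gain probability damped by the distance
#' penalty, so that for equal gains a nearer destination always wins.
#'
#' @param gain_prob probability derived from the relative economic gain.
#' @param dist_prob probability derived from the normalized distance (before
#'   the reversal; the complement is applied here).
#' @return joint probability.
#' @export
joint_prob <- function(gain_prob, dist_prob) {
  stopifnot(all(gain_prob >= 0 & gain_prob <= 1),
            all(dist_prob >= 0 & dist_prob <= 1))
  gain_prob * (1 - dist_prob)
}

#' Distance penalty probability
#'
#' Maps a normalized distance in [0, 1] onto the logistic s-curve centered at
#' 0.5 with scale 0.25, so the nearest neighbors carry a penalty close to
#' zero and the farthest close to one.
#'
#' @param d_norm normalized distance(s) in [0, 1].
#' @inheritParams logistic_prob
#' @return penalty probability in (0, 1).
#' @export
distance_prob <- function(d_norm, a = 1, b = 1) {
  logistic_prob((d_norm - 0.5) / 0.25, a, b)
}

#' Normalize probabilities into diffusion shares
#'
#' Shares are the probabilities divided by their sum, so destinations with
#' higher net gains pull a larger share of the diffused quantity. An all-zero
#' vector signals "no flow this tick" and returns an empty vector rather than
#' an error.
#'
#' @param probs non-negative probability vector.
#' @return vector of fractions summing to 1, or a zero-length vector if all
#'   probabilities are zero.
#' @examples
#' normalize_shares(c(0.2, 0.5, 0.7, 0.7))  # ~ 0.10 0.24 0.33 0.33
#' @export
normalize_shares <- function(probs) {
  if (length(probs) == 0L) return(numeric(0))
  if (any(probs < 0)) stop("domain error: probabilities must be non-negative")
  s <- sum(probs)
  if (s == 0) return(numeric(0))
  probs / s
}

#' Migration candidates and gains for one node
#'
#' For each neighbor j of node i on the population layer, the relative
#' real-income gain z_ij = (w_j/p_j - w_i/p_i) / (w_i/p_i). Only destinations
#' with a strictly positive gain are retained.
#'
#' @param net a \code{cascade_network}.
#' @param states a state snapshot data frame with columns \code{node},
#'   \code{L}, \code{w}, \code{p_F}, \code{p_G}, \code{p}, \code{alpha}
#'   (see \code{\link{state_snapshot}}).
#' @param i origin node id.
#' @return named numeric vector of positive relative gains (names are
#'   destination node ids); empty if no neighbor offers a gain.
#' @export
migration_candidates <- function(net, states, i) {
  nb <- neighbors_of(net, i, "population")
  r <- states$w / states$p
  z <- (r[nb] - r[i]) / r[i]
  keep <- z > 0
  stats::setNames(z[keep], nb[keep])
}

#' Trade candidates and profit margins for one node and good
#'
#' Producers consider their own market plus connected neighbors on the good's
#' layer, keep only markets whose price covers the unit production cost
#' (p_jk >= rho; a market exactly at cost is retained at the margin), and
#' rank them by the relative profit margin z = (p_jk - rho) / rho.
#'
#' @inheritParams migration_candidates
#' @param good \code{"F"} or \code{"G"}.
#' @param rho unit cost of production.
#' @return named numeric vector of non-negative margins over the retained
#'   destination markets (the home market included when admissible); empty if
#'   no market covers cost, in which case the producer sells nothing this
#'   tick.
#' @export
trade_candidates <- function(net, states, i, good = c("F", "G"), rho = 1) {
  good <- match.arg(good)
  layer <- if (good == "F") "food" else "nonfood"
  cand <- c(i, neighbors_of(net, i, layer))
  pk <- if (good == "F") states$p_F else states$p_G
  keep <- pk[cand] >= rho
  z <- (pk[cand[keep]] - rho) / rho
  stats::setNames(z, cand[keep])
}

#' Build a state snapshot data frame
#'
#' The per-node cross-section the candidate functions read: one row per node
#' with labor, wage, prices, price index and food share.
#'
#' @param L,w,p_F,p_G,alpha numeric vectors, one entry per node.
#' @param gamma_F,gamma_G price-index weights.
#' @return data frame with columns \code{node}, \code{L}, \code{w},
#'   \code{p_F}, \code{p_G}, \code{p}, \code{alpha}.
#' @export
state_snapshot <- function(L, w, p_F, p_G, alpha, gamma_F = 1, gamma_G = 1) {
  data.frame(node = seq_along(L), L = L, w = w, p_F = p_F, p_G = p_G,
             p = price_index(p_F, p_G, gamma_F, gamma_G), alpha = alpha)
}

#' Apply a set of directed flows to node stocks
#'
#' Population flows move workers between labor stocks; goods flows move
#' marketed quantities between inventories. Totals are conserved exactly:
#' everything shipped out arrives somewhere.
#'
#' @param stocks numeric vector of per-node stocks for the flowing quantity.
#' @param flows data frame with columns \code{src}, \code{dst}, \code{amount}
#'   (all amounts >= 0).
#' @return updated stock vector.
#' @export
apply_flows <- function(stocks, flows) {
  if (nrow(flows) == 0L) return(stocks)
  if (any(flows$amount < 0))
    stop("internal consistency error: negative flow amount")
  out <- rowsum_by(flows$amount, flows$src, length(stocks))
  if (any(out > stocks + 1e-9))
    stop("internal consistency error: flow exceeds source stock")
  stocks - out + rowsum_by(flows$amount, flows$dst, length(stocks))
}

## grouped sum onto a fixed-length vector (C-level rowsum)
rowsum_by <- function(v, g, n) {
  out <- numeric(n)
  if (length(v)) {
    s <- rowsum(v, g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}
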