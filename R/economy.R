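#' Node-level circular-flow economy primitives
#'
#' Each location runs a closed income loop every tick: labor produces real
#' output, the whole wage bill is spent on the two goods (food F, other goods
#' G), and local prices clear the market for whatever quantities are on offer.
#' These helpers are the vectorised building blocks; the simulator applies
#' them network-wide.
#'
#' @name economy
NULL

#' Real output of a node
#'
#' y = beta_F * x_F + beta_G * x_G, the product-weighted sum of the two
#' output quantities. Food producers carry weights (0.9, 0.1), non-food
#' producers (0.1, 0.9).
#'
#' @param x_F,x_G non-negative real output quantities of food and non-food.
#' @param beta_F,beta_G product weights, summing to 1.
#' @return real output y (goods units).
#' @examples
#' real_output(90, 10, 0.9, 0.1)  # 82
#' @export
real_output <- function(x_F, x_G, beta_F, beta_G) {
  if (any(x_F < 0) || any(x_G < 0))
    stop("domain error: output quantities must be non-negative")
  beta_F * x_F + beta_G * x_G
}

#' Income per worker
#'
#' w = rho * y / L: the whole value of production (at unit cost rho) is paid
#' out as wages to the L workers employed.
#'
#' @param y real output.
#' @param L labor stock, > 0.
#' @param rho unit cost of production (default 1).
#' @return wage per worker.
#' @export
wage_rate <- function(y, L, rho = 1) {
  if (any(L <= 0))
    stop("emptied-node error: wage undefined for L <= 0")
  rho * y / L
}

#' Market-clearing goods prices at a node
#'
#' A fraction alpha of total income w*L is spent on food and 1 - alpha on the
#' other good, so prices on the quantities actually marketed this tick are
#' p_F = alpha*w*L/x_F and p_G = (1-alpha)*w*L/x_G. The budget identity
#' p_F*x_F + p_G*x_G = w*L holds by construction.
#'
#' @param alpha food budget share in [0, 1].
#' @param w wage per worker.
#' @param L labor stock.
#' @param x_F,x_G strictly positive marketed quantities. The simulator floors
#'   abandoned markets at a tiny quantity before calling this (and flags them
#'   market-collapsed) rather than passing zero.
#' @return list with components \code{p_F} and \code{p_G}.
#' @export
node_prices <- function(alpha, w, L, x_F, x_G) {
  if (any(x_F <= 0) || any(x_G <= 0))
    stop("price-undefined error: marketed quantities must be positive ",
         "(the simulator floors abandoned markets)")
  list(p_F = alpha * w * L / x_F, p_G = (1 - alpha) * w * L / x_G)
}

#' Average price index of a node
#'
#' The weighted mean of the K = 2 goods prices, p = (gamma_F p_F +
#' gamma_G p_G) / 2, with equal unit weights by default.
#'
#' @param p_F,p_G non-negative goods prices.
#' @param gamma_F,gamma_G index weights (default 1 each).
#' @return price index p.
#' @export
price_index <- function(p_F, p_G, gamma_F = 1, gamma_G = 1) {
  if (any(p_F < 0) || any(p_G < 0))
    stop("domain error: prices must be non-negative")
  (gamma_F * p_F + gamma_G * p_G) / 2
}

#' Nominal output of a node
#'
#' Y = x_F p_F + x_G p_G, the market value of everything produced. In autarky
#' it equals the wage bill w*L.
#'
#' @inheritParams node_prices
#' @param p_F,p_G goods prices.
#' @return nominal output Y.
#' @export
nominal_output <- function(x_F, x_G, p_F, p_G) {
  if (any(x_F < 0) || any(x_G < 0) || any(p_F < 0) || any(p_G < 0))
    stop("domain error: inputs must be non-negative")
  x_F * p_F + x_G * p_G
}

#' Endogenous food budget share
#'
#' Households defend a minimum per-capita food bundle c_bar: the share of
#' income needed to buy it at current prices is p_F * c_bar * L / (w * L),
#' floored at the subsistence share alpha_min and capped at 1 (households
#' cannot spend more than they earn; a node stuck at the cap cannot afford
#' c_bar and is food-insecure).
#'
#' @param p_F local food price.
#' @param w wage per worker (> 0 requires a populated node).
#' @param L labor stock, > 0.
#' @param c_bar minimum per-capita food bundle (goods units per worker).
#' @param alpha_min lower bound on the food share.
#' @return updated share alpha in [alpha_min, 1].
#' @examples
#' update_alpha(p_F = 1, w = 1, L = 100, c_bar = 0.4, alpha_min = 0.3)  # 0.4
#' @export
update_alpha <- function(p_F, w, L, c_bar, alpha_min) {
  if (any(w * L <= 0))
    stop("emptied-node error: alpha undefined for w * L <= 0")
  pmin(pmax(p_F * c_bar * L / (w * L), alpha_min), 1)
}
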