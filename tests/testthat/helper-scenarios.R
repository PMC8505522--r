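## Small shared scenarios and state builders used across test files.

quick_scenario <- function(n = 20L, deg = 4, seed = 1L, t_max = 1500L, ...) {
  cascade_scenario(network = list(n_nodes = n, target_mean_degree = deg),
                   convergence = list(t_max = t_max), seed = seed, ...)
}

## uniform snapshot: every node identical
uniform_snapshot <- function(n, L = 100, w = 1, p_F = 1, p_G = 1, alpha = 0.5) {
  state_snapshot(L = rep(L, n), w = rep(w, n), p_F = rep(p_F, n),
                 p_G = rep(p_G, n), alpha = rep(alpha, n))
}

## fresh initial state list for cascade_tick() on a manual network
fresh_state <- function(net, sc = cascade_scenario()) {
  ec <- sc$economy
  food <- net$producer_type == "food"
  x_F <- ifelse(food, ec$x_food[1], ec$x_nonfood[1])
  x_G <- ifelse(food, ec$x_food[2], ec$x_nonfood[2])
  bF <- ifelse(food, ec$beta_food[1], ec$beta_food[2])
  y <- real_output(x_F, x_G, bF, 1 - bF)
  L <- rep(ec$L0, length(net$nodes))
  w <- wage_rate(y, L, ec$rho)
  pr <- node_prices(ec$alpha0, w, L, x_F, x_G)
  list(L = L, x_F = x_F, x_G = x_G, alpha = rep(ec$alpha0, length(L)),
       w = w, p_F = pr$p_F, p_G = pr$p_G)
}

## a 4-node ring used by several vrank tests
ring4 <- function(types = c("food", "nonfood", "food", "nonfood")) {
  manual_network(rbind(c(.3, .3), c(.7, .3), c(.7, .7), c(.3, .7)),
                 rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)), types)
}
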