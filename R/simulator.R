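## Time-stepping engine: burn-in to the pre-shock equilibrium, shock
## application, post-shock evolution to convergence. All node updates within a
## tick are synchronous (computed from start-of-tick snapshots), in the order
## production -> wages -> trade -> market clearing -> budget share -> migration.

Q_FLOOR <- 1e-9    # quantity floor protecting prices on abandoned markets
L_FLOOR <- 1e-9    # division floor for depopulated nodes
TRADE_SEED <- 0.01 # re-entry seed share for markets priced above cost
M_COLLAPSE <- 1e-6 # transaction volume below which a market counts as collapsed
Q_SIGNAL <- 1      # minimum quote volume (goods units) behind a price signal

## Precompute slot index arrays for the vectorised tick. Trade slots for a
## good are (home, ->neighbor, <-neighbor) on that good's layer; migration
## slots are the directed population-layer edges.
build_sim <- function(net, cfg) {
  n <- length(net$nodes)
  trade_slots <- function(layer) {
    e <- net$edges[net$layers[[layer]], , drop = FALSE]
    src <- c(seq_len(n), e[, 1L], e[, 2L])
    dst <- c(seq_len(n), e[, 2L], e[, 1L])
    dn <- numeric(length(src))          # normalized distance per slot
    if (nrow(e)) {
      d <- net$dist[cbind(src, dst)]
      mx <- rowsum_by_max(d, src, n)
      dn <- ifelse(mx[src] > 0, d / mx[src], 0)
    }
    list(src = src, dst = dst, dnorm = dn,
         gsrc = make_grouper(src, n), gdst = make_grouper(dst, n))
  }
  e <- net$edges[net$layers$population, , drop = FALSE]
  msrc <- c(e[, 1L], e[, 2L])
  mdst <- c(e[, 2L], e[, 1L])
  d <- net$dist[cbind(msrc, mdst)]
  mx <- rowsum_by_max(d, msrc, n)
  mdnorm <- d / mx[msrc]
  food <- net$producer_type == "food"
  bF <- ifelse(food, cfg$economy$beta_food[1L], cfg$economy$beta_food[2L])
  list(n = n,
       F = trade_slots("food"), G = trade_slots("nonfood"),
       msrc = msrc, mdst = mdst, mdnorm = mdnorm,
       gmsrc = make_grouper(msrc, n), gmdst = make_grouper(mdst, n),
       msplit = split(seq_along(msrc), factor(msrc, levels = seq_len(n))),
       beta_F = bF, beta_G = 1 - bF)
}

rowsum_by_max <- function(v, g, n) {
  out <- numeric(n)
  if (!length(v)) return(out)
  agg <- tapply(v, g, max)
  out[as.integer(names(agg))] <- agg
  out
}

## Precomputed grouped-sum machinery for the fixed slot->node groupings used
## every tick: a permutation sorting by group plus group boundaries, so each
## per-tick aggregation is one cumsum instead of a full rowsum.
make_grouper <- function(g, n) {
  if (!length(g))
    return(list(ord = integer(0), ends = integer(0), ids = integer(0), n = n))
  ord <- order(g)
  gs <- g[ord]
  ends <- which(c(gs[-1L] != gs[-length(gs)], TRUE))
  list(ord = ord, ends = ends, ids = gs[ends], n = n)
}

sum_g <- function(v, gr) {
  cs <- cumsum(v[gr$ord])
  out <- numeric(gr$n)
  tot <- cs[gr$ends]
  out[gr$ids] <- tot - c(0, tot[-length(tot)])
  out
}

## Initial node state: equal labor everywhere, producer-type output mix,
## initial prices from marketing the full output at the initial budget share.
init_state <- function(net, sim, cfg) {
  ec <- cfg$economy
  n <- sim$n
  food <- net$producer_type == "food"
  x_F <- ifelse(food, ec$x_food[1L], ec$x_nonfood[1L])
  x_G <- ifelse(food, ec$x_food[2L], ec$x_nonfood[2L])
  L <- rep(ec$L0, n)
  y <- real_output(x_F, x_G, sim$beta_F, sim$beta_G)
  w <- wage_rate(y, L, ec$rho)
  pr <- node_prices(ec$alpha0, w, L, x_F, x_G)
  eq_shares <- function(sl) {
    cnt <- rowsum_by(rep(1, length(sl$src)), sl$src, n)
    1 / cnt[sl$src]
  }
  list(L = L, x_F = x_F, x_G = x_G, alpha = rep(ec$alpha0, n),
       w = w, p_F = pr$p_F, p_G = pr$p_G,
       p = price_index(pr$p_F, pr$p_G, ec$gamma_F, ec$gamma_G),
       s_F = eq_shares(sim$F), s_G = eq_shares(sim$G),
       wh_F = rep(ec$x_food[1L], n), wh_G = rep(ec$x_nonfood[2L], n))
}

## One good's trade round: destination filter by previous-tick prices
## (p >= rho), supply shares adjusted multiplicatively to relative prices
## (replicator-style tatonnement: markets above cost gain share in proportion
## to their price, markets at cost keep theirs, excluded markets re-enter
## through a small seed weight), mu-smoothed share inertia, then absorption
## rationing: a market accepts goods only up to spend/rho, the quantity that
## keeps its price at or above unit cost; excess is withheld at the source.
trade_good <- function(x, spend, p_prev, s_prev, wh_prev, sl, n, cfg) {
  rho <- cfg$economy$rho
  mu <- cfg$diffusion$mu
  cand <- p_prev[sl$dst] >= rho * (1 - 1e-12)
  prel <- p_prev[sl$dst] / rho
  ## re-entry floor: a producer sitting on withheld stock probes above-cost
  ## markets with at least a seed weight, so abandoned destinations can be
  ## re-discovered; established shares and sold-out producers are unaffected,
  ## so the seed does not bias stationary allocations
  probing <- wh_prev[sl$src] > 1e-9
  base <- pmax(s_prev, TRADE_SEED * (probing & prel > 1 + 1e-9))
  wgt <- base * prel * cand
  if (cfg$diffusion$trade_use_distance)
    wgt <- wgt * (1 - distance_prob(sl$dnorm, cfg$diffusion$a,
                                    cfg$diffusion$b))
  sw <- sum_g(wgt, sl$gsrc)[sl$src]
  ## no weight at all (e.g. first admissible tick) -> fall back to current
  ## shares so the allocation the signals last produced persists
  target <- s_prev
  hit <- sw > 0
  target[hit] <- wgt[hit] / sw[hit]
  s <- (1 - mu) * s_prev + mu * target
  s <- s * cand
  norm <- sum_g(s, sl$gsrc)[sl$src]
  ok <- norm > 0
  s[ok] <- s[ok] / norm[ok]
  s[!ok] <- 0

  desired <- x[sl$src] * s
  inflow <- sum_g(desired, sl$gdst)
  cap <- spend / rho
  f <- pmin(1, cap / pmax(inflow, Q_FLOOR))
  acc <- desired * f[sl$dst]
  marketed <- sum_g(acc, sl$gdst)
  sold <- sum_g(acc, sl$gsrc)
  list(marketed = marketed, withheld = pmax(x - sold, 0), shares = s,
       flows = acc)
}

## Full synchronous tick on the vectorised state; returns the updated state
## and the per-tick record row.
step_state <- function(st, sim, cfg) {
  ec <- cfg$economy; df <- cfg$diffusion
  n <- sim$n

  ## (1) production at capacity, (2) wages
  y <- sim$beta_F * st$x_F + sim$beta_G * st$x_G
  L <- st$L
  w <- ec$rho * y / pmax(L, L_FLOOR)

  ## (3) trade flows per good, (4) market clearing
  spend_F <- st$alpha * w * L
  spend_G <- (1 - st$alpha) * w * L
  tF <- trade_good(st$x_F, spend_F, st$p_F, st$s_F, st$wh_F, sim$F, n, cfg)
  tG <- trade_good(st$x_G, spend_G, st$p_G, st$s_G, st$wh_G, sim$G, n, cfg)
  ## market clearing: prices are quoted on at least one goods unit of volume,
  ## so a starved market posts a high but bounded signal (at most the local
  ## spending) instead of a quantity-floor artifact; markets with essentially
  ## no transactions are flagged collapsed
  coll_F <- tF$marketed < M_COLLAPSE | spend_F < M_COLLAPSE
  coll_G <- tG$marketed < M_COLLAPSE | spend_G < M_COLLAPSE
  p_F <- spend_F / pmax(tF$marketed, Q_SIGNAL)
  p_G <- spend_G / pmax(tG$marketed, Q_SIGNAL)
  p <- price_index(p_F, p_G, ec$gamma_F, ec$gamma_G)

  ## (5) endogenous food budget share, relaxed toward the defended-bundle
  ## share at the same behavioral adjustment rate mu as the flow margins
  ## (the fixed point is the threshold share itself)
  alpha <- (1 - df$mu) * st$alpha +
    df$mu * update_alpha(p_F, w, L, ec$c_bar, ec$alpha_min)

  ## (6) migration: positive relative real-income gains, gravity shares,
  ## outflow mu * L scaled by the best gain (saturating at gains >= 100%)
  r <- w / p
  z <- (r[sim$mdst] - r[sim$msrc]) / r[sim$msrc]
  pos <- z > 0 & L[sim$msrc] >= 1
  Pi <- numeric(length(z))
  if (any(pos)) {
    Piq <- logistic_prob(z[pos] / df$gain_scale, df$a, df$b)
    Pi[pos] <- joint_prob(Piq, distance_prob(sim$mdnorm[pos], df$a, df$b))
  }
  sPi <- sum_g(Pi, sim$gmsrc)[sim$msrc]
  shares <- numeric(length(Pi))
  ok <- sPi > 0
  shares[ok] <- Pi[ok] / sPi[ok]
  maxz <- vapply(sim$msplit, function(ix) {
    zz <- z[ix][pos[ix]]
    if (length(zz)) max(zz) else 0
  }, numeric(1L))
  outflow_tot <- df$mu * L * pmin(maxz, 1)
  flow <- outflow_tot[sim$msrc] * shares
  if (cfg$mode == "sampled") {
    for (i in which(outflow_tot > 0)) {
      ix <- sim$msplit[[i]]
      sh <- shares[ix]
      if (sum(sh) > 0) {
        nmig <- floor(outflow_tot[i])
        cnt <- as.numeric(stats::rmultinom(1L, nmig, sh))
        flow[ix] <- cnt
      }
    }
    outflow_tot <- sum_g(flow, sim$gmsrc)
  }
  L_new <- L - sum_g(flow, sim$gmsrc) + sum_g(flow, sim$gmdst)

  cons <- alpha * w / p_F
  st$L <- L_new; st$alpha <- alpha
  st$w <- w; st$p_F <- p_F; st$p_G <- p_G; st$p <- p
  st$s_F <- tF$shares; st$s_G <- tG$shares
  st$wh_F <- tF$withheld; st$wh_G <- tG$withheld

  list(state = st,
       record = list(L = L, w = w, p_F = p_F, p_G = p_G, p = p,
                     alpha = alpha, cons = cons,
                     m_F = tF$marketed, m_G = tG$marketed,
                     wh_F = tF$withheld, wh_G = tG$withheld,
                     coll_F = as.numeric(coll_F), coll_G = as.numeric(coll_G)))
}

#' Advance a node-state snapshot by one synchronous tick
#'
#' One full model tick on an explicit state: production at capacity, wages,
#' trade candidate selection and goods flows, market clearing, budget-share
#' update, migration. All nodes update from the same start-of-tick snapshot.
#' This is the single-step entry point used for small worked examples and
#' cross-checks; \code{\link{run_cascade}} drives the same update in a loop.
#'
#' @param state list with per-node vectors \code{L}, \code{x_F}, \code{x_G},
#'   \code{alpha}, \code{p_F}, \code{p_G} (and optionally the share memory
#'   \code{s_F}, \code{s_G} from a previous call).
#' @param net a \code{cascade_network}.
#' @param params a \code{cascade_scenario} (its network block is ignored).
#' @return list with the updated \code{state} and the tick \code{record}
#'   (wages, prices, marketed and withheld quantities, consumption).
#' @export
cascade_tick <- function(state, net, params) {
  sim <- build_sim(net, params)
  if (is.null(state$s_F)) {
    st0 <- init_state(net, sim, params)
    state$s_F <- st0$s_F
    state$s_G <- st0$s_G
  }
  if (is.null(state$wh_F)) state$wh_F <- state$x_F
  if (is.null(state$wh_G)) state$wh_G <- state$x_G
  if (is.null(state$w)) {
    y <- sim$beta_F * state$x_F + sim$beta_G * state$x_G
    state$w <- params$economy$rho * y / pmax(state$L, L_FLOOR)
  }
  if (is.null(state$p))
    state$p <- price_index(state$p_F, state$p_G, params$economy$gamma_F,
                           params$economy$gamma_G)
  out <- step_state(state, sim, params)
  if (any(!is.finite(out$state$L)) || any(out$state$L < 0))
    stop("tick failure: non-finite or negative labor stock")
  out
}

#' Apply the disaster shock to food output capacities
#'
#' Multiplies the food output of every epicenter food node by (1 - s). The
#' loss is permanent: capacities are not restored during the run.
#'
#' @param state state list with an \code{x_F} vector (as in
#'   \code{\link{cascade_tick}}).
#' @param epicenter_food_nodes integer ids of the shocked food producers.
#' @param s output-loss fraction in [0, 1].
#' @return the state with reduced \code{x_F}.
#' @export
apply_shock <- function(state, epicenter_food_nodes, s) {
  stopifnot(s >= 0, s <= 1)
  state$x_F[epicenter_food_nodes] <- state$x_F[epicenter_food_nodes] * (1 - s)
  state
}

## Iterate the tick until wages and price indices stabilise (max relative
## per-tick change below tol for `window` consecutive ticks) or t_max.
iterate_phase <- function(st, sim, cfg, t_max = cfg$convergence$t_max) {
  tol <- cfg$convergence$tol
  window <- cfg$convergence$window
  n <- sim$n
  vars <- c("L", "w", "p_F", "p_G", "p", "alpha", "cons", "m_F", "m_G",
            "wh_F", "wh_G", "coll_F", "coll_G")
  rec <- lapply(vars, function(v) matrix(NA_real_, nrow = t_max, ncol = n))
  names(rec) <- vars
  prev <- c(st$w, st$p)
  streak <- 0L
  converged <- FALSE
  t_used <- 0L
  for (t in seq_len(t_max)) {
    out <- step_state(st, sim, cfg)
    st <- out$state
    if (any(!is.finite(st$L)) || any(st$L < -1e-9))
      stop("tick failure at t=", t, ": non-finite or negative labor stock")
    for (v in vars) rec[[v]][t, ] <- out$record[[v]]
    cur <- c(out$record$w, out$record$p)
    relch <- max(abs(cur - prev) / pmax(abs(prev), 1e-12))
    prev <- cur
    streak <- if (relch < tol) streak + 1L else 0L
    t_used <- t
    if (streak >= window) { converged <- TRUE; break }
  }
  for (v in vars) rec[[v]] <- rec[[v]][seq_len(t_used), , drop = FALSE]
  list(state = st, records = rec, ticks = t_used, converged = converged)
}

## Burn-in phase shared by all shock levels of one network.
burn_in <- function(scenario) {
  cfg <- scenario
  net <- generate_network(cfg$network$n_nodes, cfg$network$food_frac,
                          cfg$network$target_mean_degree, seed = cfg$seed)
  epi <- select_epicenter(net, cfg$shock$epicenter_center,
                          epicenter_radius(net, cfg$shock$epicenter_center,
                                           cfg$shock$epicenter_frac))
  sim <- build_sim(net, cfg)
  st <- init_state(net, sim, cfg)
  ph <- iterate_phase(st, sim, cfg)
  list(scenario = cfg, net = net, sim = sim, epicenter = epi,
       state = ph$state, records = ph$records, ticks = ph$ticks,
       converged = ph$converged)
}

## Post-shock continuation from a completed burn-in.
continue_cascade <- function(burn, s) {
  cfg <- burn$scenario
  cfg$shock$s <- s
  st <- apply_shock(burn$state, attr(burn$epicenter, "food_nodes"), s)
  if (cfg$mode == "sampled") set.seed(cfg$seed + 104729L)
  ph <- iterate_phase(st, burn$sim, cfg)
  rec <- mapply(rbind, burn$records, ph$records, SIMPLIFY = FALSE)
  structure(list(
    panel = rec, net = burn$net, scenario = cfg, epicenter = burn$epicenter,
    shock_tick = burn$ticks,
    manifest = list(seed = cfg$seed, config_checksum = config_checksum(cfg),
                    mode = cfg$mode, shock = s,
                    burn_ticks = burn$ticks, post_ticks = ph$ticks,
                    converged_burn = burn$converged,
                    converged_post = ph$converged,
                    unconverged = !(burn$converged && ph$converged))
  ), class = "cascade_run")
}

#' Run one full disaster-cascade simulation
#'
#' Generates the network from the scenario seed, runs the burn-in to the
#' pre-shock equilibrium (wages and price indices stable to the configured
#' tolerance), applies the food-output shock to the epicenter's food
#' producers, and evolves the system to the post-shock equilibrium or
#' \code{t_max}. Non-convergence is reported in the manifest
#' (\code{unconverged} flag), not raised as an error.
#'
#' @param scenario a \code{\link{cascade_scenario}}.
#' @return an object of class \code{cascade_run}: the node-by-tick panel
#'   (labor, wages, prices, price index, budget share, per-capita food
#'   consumption, marketed and withheld quantities), the network, the
#'   epicenter, the tick at which the shock hit, and a run manifest (seed,
#'   config checksum, convergence ticks and flags).
#' @examples
#' sc <- cascade_scenario(network = list(n_nodes = 15, target_mean_degree = 4),
#'                        convergence = list(t_max = 300))
#' run <- run_cascade(sc)
#' run$manifest$burn_ticks
#' @export
run_cascade <- function(scenario) {
  stopifnot(inherits(scenario, "cascade_scenario"))
  continue_cascade(burn_in(scenario), scenario$shock$s)
}

#' Enumerate the shock-sweep experiment grid
#'
#' The default experiment crosses shock levels \{0.4, 0.5, 0.6, 0.7, 0.8\}
#' with 10 random networks: 50 runs, plus one no-shock baseline per network
#' for percent-change reporting.
#'
#' @param shock_levels numeric vector of output-loss fractions.
#' @param n_networks number of random networks per level.
#' @param base_seed seed of the first network; network k uses
#'   \code{base_seed + k - 1}.
#' @return data frame with one row per run: \code{network}, \code{seed},
#'   \code{s}, \code{baseline} flag.
#' @examples
#' nrow(subset(sweep_grid(), !baseline))  # 50
#' @export
sweep_grid <- function(shock_levels = seq(0.4, 0.8, by = 0.1),
                       n_networks = 10L, base_seed = 1L) {
  stopifnot(length(shock_levels) > 0L, n_networks >= 1L)
  g <- expand.grid(s = c(0, shock_levels), network = seq_len(n_networks))
  data.frame(network = g$network, seed = base_seed + g$network - 1L,
             s = g$s, baseline = g$s == 0)
}

#' Run the shock-sweep experiment
#'
#' For each random network (one seed per network) the burn-in is computed
#' once and reused for every shock level plus the no-shock baseline, so all
#' continuations of one network branch from the identical pre-shock
#' equilibrium. Individual runs that fail to converge are flagged in their
#' manifests; the grid never aborts on one run.
#'
#' @param scenario base \code{\link{cascade_scenario}}; its seed is the seed
#'   of the first network.
#' @param shock_levels numeric vector of output-loss fractions (default the
#'   reference grid 0.4--0.8 by 0.1).
#' @param n_networks number of random networks (default 10).
#' @return object of class \code{cascade_sweep}: list with the run
#'   enumeration (\code{grid}), and \code{runs}, a list indexed
#'   \code{[[network]][[as.character(s)]]} of \code{cascade_run} objects
#'   (baseline under \code{"0"}).
#' @export
sweep_cascade <- function(scenario = cascade_scenario(),
                          shock_levels = seq(0.4, 0.8, by = 0.1),
                          n_networks = 10L) {
  grid <- sweep_grid(shock_levels, n_networks, base_seed = scenario$seed)
  runs <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    sc <- scenario
    sc$seed <- scenario$seed + k - 1L
    sc <- structure(sc, class = "cascade_scenario")
    burn <- burn_in(sc)
    levels_k <- c(0, shock_levels)
    runs[[k]] <- stats::setNames(
      lapply(levels_k, function(s) continue_cascade(burn, s)),
      as.character(levels_k))
  }
  structure(list(grid = grid, runs = runs,
                 shock_levels = shock_levels, n_networks = n_networks),
            class = "cascade_sweep")
}

#' @export
print.cascade_sweep <- function(x, ...) {
  cat("Cascade shock sweep\n")
  cat(sprintf("  %d shock levels x %d networks = %d runs (+%d baselines)\n",
              length(x$shock_levels), x$n_networks,
              length(x$shock_levels) * x$n_networks, x$n_networks))
  conv <- vapply(unlist(x$runs, recursive = FALSE),
                 function(r) !r$manifest$unconverged, logical(1L))
  cat(sprintf("  converged: %d / %d\n", sum(conv), length(conv)))
  invisible(x)
}
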