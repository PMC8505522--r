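#' VRank: multi-layer vulnerability index of one node
#'
#' VRank is a dampened geometric mean of a node's own minimum-bundle-cost to
#' income ratio and the aggregate ratio of its neighbors:
#' \deqn{VRank_{it} = \left[\frac{p_{it}\,\bar c L_i}{w_{it} L_{it}}\;\beta\;
#'   \frac{\sum_{j\ne i} p_{jt}\,\bar c L_j}{\sum_{j\ne i} w_{jt} L_{jt}}
#'   \right]^{1/2}}
#' where p is the node price index, \eqn{\bar c L} the node-level minimum
#' food bundle (per-capita bundle times workers), wL total income, and j runs
#' over the node's neighbors in the union graph of all three layers. Higher
#' values mean higher vulnerability. For an isolated node the neighbor term is
#' unavailable; the own-ratio-only fallback \eqn{r\sqrt{\beta}} is returned
#' with attribute \code{isolated = TRUE}.
#'
#' @param i node id.
#' @param states state snapshot data frame (see \code{\link{state_snapshot}})
#'   with columns \code{L}, \code{w}, \code{p}.
#' @param net a \code{cascade_network}.
#' @param c_bar minimum per-capita food bundle.
#' @param beta_damp dampening factor (default 0.85).
#' @return VRank value (non-negative scalar).
#' @examples
#' # all nodes identical with bundle-cost/income ratio r: VRank = r * sqrt(beta)
#' @export
vrank_node <- function(i, states, net, c_bar, beta_damp = 0.85) {
  own <- states$p[i] * c_bar * states$L[i] /
    pmax(states$w[i] * states$L[i], 1e-12)
  nb <- neighbors_of(net, i, "union")
  if (length(nb) == 0L) {
    return(structure(own * sqrt(beta_damp), isolated = TRUE))
  }
  neigh <- sum(states$p[nb] * c_bar * states$L[nb]) /
    pmax(sum(states$w[nb] * states$L[nb]), 1e-12)
  sqrt(own * beta_damp * neigh)
}

#' VRank panel over a full simulation run
#'
#' Computes the index for every node at every recorded tick, plus the percent
#' change relative to each node's own value at the last pre-shock tick (the
#' converged baseline level).
#'
#' @param run a \code{cascade_run}.
#' @param beta_damp dampening factor (default 0.85).
#' @param c_bar minimum bundle; defaults to the run's scenario value.
#' @return object of class \code{vrank_series}: list with tick-by-node
#'   matrices \code{vrank}, \code{pct_change}, \code{own_ratio},
#'   \code{neighbor_ratio}, the \code{shock_tick} and parameters.
#' @export
vrank_panel <- function(run, beta_damp = 0.85,
                        c_bar = run$scenario$economy$c_bar) {
  stopifnot(inherits(run, "cascade_run"))
  net <- run$net
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  e <- net$edges[sort(unique(unlist(net$layers))), , drop = FALSE]
  A[cbind(e[, 1L], e[, 2L])] <- 1
  A[cbind(e[, 2L], e[, 1L])] <- 1

  P <- run$panel$p; W <- run$panel$w; L <- run$panel$L
  own <- P * c_bar / pmax(W, 1e-12)            # p c_bar L / (w L)
  num <- (P * L) %*% A                         # sum_j p_j c_bar L_j (/c_bar)
  den <- (W * L) %*% A
  neigh <- c_bar * num / pmax(den, 1e-12)
  v <- sqrt(own * beta_damp * neigh)
  base <- v[run$shock_tick, ]
  pct <- 100 * sweep(v, 2L, base, "-") / rep(base, each = nrow(v))
  structure(list(vrank = v, pct_change = pct, own_ratio = own,
                 neighbor_ratio = neigh, shock_tick = run$shock_tick,
                 beta_damp = beta_damp, c_bar = c_bar),
            class = "vrank_series")
}

#' @export
print.vrank_series <- function(x, ...) {
  tt <- nrow(x$vrank)
  cat("VRank series\n")
  cat(sprintf("  %d ticks x %d nodes, beta = %.2f, shock at tick %d\n",
              tt, ncol(x$vrank), x$beta_damp, x$shock_tick))
  cat(sprintf("  final mean VRank %.4f (baseline %.4f)\n",
              mean(x$vrank[tt, ]), mean(x$vrank[x$shock_tick, ])))
  invisible(x)
}

#' @export
as.data.frame.vrank_series <- function(x, ...) {
  tt <- nrow(x$vrank); n <- ncol(x$vrank)
  data.frame(tick = rep(seq_len(tt), n),
             node = rep(seq_len(n), each = tt),
             vrank = as.vector(x$vrank),
             pct_change = as.vector(x$pct_change),
             own_ratio = as.vector(x$own_ratio),
             neighbor_ratio = as.vector(x$neighbor_ratio))
}
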