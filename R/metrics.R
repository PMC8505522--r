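#' Baseline-relative vulnerability indicators
#'
#' The two headline indicators of the analysis, per node and tick: the
#' food-to-labor price ratio p_F / w (affordability stress: rising food
#' prices and/or falling incomes) and per-capita real food consumption
#' alpha * w / p_F; both raw and as percent change against the no-shock
#' baseline run on the same network.
#'
#' @param run a \code{cascade_run} (the shocked trajectory).
#' @param baseline the no-shock \code{cascade_run} sharing the network, seed
#'   and burn-in (e.g. the \code{"0"} entry of a sweep).
#' @return object of class \code{indicator_panel}: tick-by-node matrices
#'   \code{ratio}, \code{cons}, \code{ratio_pct}, \code{cons_pct}, plus
#'   \code{shock_tick} and the network. Baseline ticks beyond the baseline
#'   run's converged end reuse its final (stationary) values.
#' @export
indicators <- function(run, baseline) {
  stopifnot(inherits(run, "cascade_run"), inherits(baseline, "cascade_run"))
  if (run$manifest$seed != baseline$manifest$seed ||
      run$shock_tick != baseline$shock_tick)
    stop("pairing error: run and baseline must share network, seed and burn-in")
  ratio <- run$panel$p_F / run$panel$w
  cons <- run$panel$cons
  bratio <- baseline$panel$p_F / baseline$panel$w
  bcons <- baseline$panel$cons
  tt <- nrow(ratio)
  pick <- pmin(seq_len(tt), nrow(bratio))   # hold converged baseline constant
  ratio_pct <- 100 * (ratio - bratio[pick, , drop = FALSE]) /
    bratio[pick, , drop = FALSE]
  cons_pct <- 100 * (cons - bcons[pick, , drop = FALSE]) /
    bcons[pick, , drop = FALSE]
  structure(list(ratio = ratio, cons = cons,
                 ratio_pct = ratio_pct, cons_pct = cons_pct,
                 shock_tick = run$shock_tick, net = run$net,
                 epicenter = run$epicenter, s = run$manifest$shock),
            class = "indicator_panel")
}

#' Post-shock summary of an indicator panel
#'
#' Time means (over the post-shock phase) and peaks of the spatial-mean
#' percent changes: the per-run numbers the box-plot summaries aggregate.
#'
#' @param ind an \code{indicator_panel}.
#' @return list with \code{mean_ratio_pct}, \code{mean_cons_pct},
#'   \code{peak_ratio_pct}, \code{trough_cons_pct}, \code{final_ratio_pct},
#'   \code{final_cons_pct}.
#' @export
indicator_summary <- function(ind) {
  tt <- nrow(ind$ratio_pct)
  post <- seq(ind$shock_tick + 1L, tt)
  mr <- rowMeans(ind$ratio_pct[post, , drop = FALSE])
  mc <- rowMeans(ind$cons_pct[post, , drop = FALSE])
  list(mean_ratio_pct = mean(mr), mean_cons_pct = mean(mc),
       peak_ratio_pct = max(mr), trough_cons_pct = min(mc),
       final_ratio_pct = mr[length(mr)], final_cons_pct = mc[length(mc)])
}

#' Per-run indicator summaries for a whole sweep
#'
#' @param sw a \code{cascade_sweep}.
#' @return data frame with one row per (network, shock level): the
#'   \code{\link{indicator_summary}} quantities, ready for box-plot style
#'   aggregation (medians, inter-quartile ranges, outliers) across networks.
#' @export
sweep_indicators <- function(sw) {
  stopifnot(inherits(sw, "cascade_sweep"))
  out <- list()
  for (k in seq_len(sw$n_networks)) {
    base <- sw$runs[[k]][["0"]]
    for (s in sw$shock_levels) {
      ind <- indicators(sw$runs[[k]][[as.character(s)]], base)
      sm <- indicator_summary(ind)
      out[[length(out) + 1L]] <- data.frame(network = k, s = s,
                                            as.data.frame(sm))
    }
  }
  do.call(rbind, out)
}

#' Distance-by-density heat bins of an indicator
#'
#' Tracks the spatial evolution of an indicator at regular post-shock
#' snapshots on a grid of normalized distance to the epicenter (0 =
#' epicenter, 1 = farthest location) by node density (union-graph degree,
#' quantile-binned so every bin is populated). Cell values are means over the
#' nodes in the cell; empty cells are NA, not zero.
#'
#' @param ind an \code{indicator_panel}.
#' @param value which indicator: \code{"ratio_pct"}, \code{"cons_pct"},
#'   \code{"ratio"} or \code{"cons"}.
#' @param n_dist_bins,n_dens_bins bin counts (>= 1).
#' @param snapshot_ticks ticks to snapshot; default 8 evenly spaced ticks
#'   across the post-shock phase.
#' @return object of class \code{heat_bin_grid}: a 3-d array
#'   [distance bin, density bin, snapshot] of cell means, with bin
#'   assignments, counts and snapshot ticks attached.
#' @export
heat_bins <- function(ind, value = "ratio_pct", n_dist_bins = 5L,
                      n_dens_bins = 3L, snapshot_ticks = NULL) {
  stopifnot(inherits(ind, "indicator_panel"))
  if (n_dist_bins < 1L || n_dens_bins < 1L)
    stop("configuration error: bin counts must be >= 1")
  mat <- ind[[value]]
  tt <- nrow(mat)
  if (is.null(snapshot_ticks))
    snapshot_ticks <- unique(round(seq(ind$shock_tick + 1L, tt, length.out = 8L)))
  if (any(snapshot_ticks < 1L | snapshot_ticks > tt))
    stop("snapshot ticks outside the trajectory")

  net <- ind$net
  centroid <- colMeans(net$coords[ind$epicenter, , drop = FALSE])
  d <- sqrt((net$coords[, 1L] - centroid[1L])^2 +
            (net$coords[, 2L] - centroid[2L])^2)
  d[ind$epicenter] <- 0                      # epicenter members sit in bin 0
  dn <- d / max(d)
  dist_bin <- pmin(pmax(ceiling(dn * n_dist_bins), 1L), n_dist_bins)
  dist_bin[dn == 0] <- 1L

  deg <- net$degree$union
  qs <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_dens_bins + 1L)))
  dens_bin <- as.integer(cut(deg, breaks = qs, include.lowest = TRUE))
  n_dens_eff <- length(qs) - 1L

  arr <- array(NA_real_, dim = c(n_dist_bins, n_dens_eff,
                                 length(snapshot_ticks)))
  cnt <- matrix(0L, n_dist_bins, n_dens_eff)
  for (i in seq_along(dist_bin))
    cnt[dist_bin[i], dens_bin[i]] <- cnt[dist_bin[i], dens_bin[i]] + 1L
  for (k in seq_along(snapshot_ticks)) {
    v <- mat[snapshot_ticks[k], ]
    sums <- matrix(0, n_dist_bins, n_dens_eff)
    for (i in seq_along(v))
      sums[dist_bin[i], dens_bin[i]] <- sums[dist_bin[i], dens_bin[i]] + v[i]
    arr[, , k] <- ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  structure(arr, class = "heat_bin_grid", value = value,
            snapshot_ticks = snapshot_ticks, dist_bin = dist_bin,
            dens_bin = dens_bin, counts = cnt)
}

#' @export
print.heat_bin_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Heat-bin grid of %s: %d distance bins x %d density bins x %d snapshots\n",
              attr(x, "value"), d[1L], d[2L], d[3L]))
  cat("  snapshot ticks:", paste(attr(x, "snapshot_ticks"), collapse = ", "), "\n")
  invisible(x)
}

#' Adjustment-cycle trace in the (ratio, consumption) plane
#'
#' The time-ordered path of the spatial-mean indicator percent changes from
#' the shock tick to the end of the run, with a signed-area orientation
#' diagnostic: the loop integral of cons d(ratio), negative for a
#' counter-clockwise cycle in the (ratio, consumption) plane.
#'
#' @param ind an \code{indicator_panel}.
#' @return object of class \code{cycle_trace}: list with \code{path} (data
#'   frame tick / ratio_pct / cons_pct), \code{signed_area},
#'   \code{orientation} (\code{"counter-clockwise"} when the area is
#'   negative) and \code{amplitude} (largest axis range of the loop).
#' @export
cycle_trace <- function(ind) {
  stopifnot(inherits(ind, "indicator_panel"))
  tt <- nrow(ind$ratio_pct)
  ticks <- seq(ind$shock_tick, tt)
  x <- rowMeans(ind$ratio_pct[ticks, , drop = FALSE])
  y <- rowMeans(ind$cons_pct[ticks, , drop = FALSE])
  area <- signed_area(x, y)
  structure(list(path = data.frame(tick = ticks, ratio_pct = x, cons_pct = y),
                 signed_area = area,
                 orientation = if (area < 0) "counter-clockwise" else "clockwise",
                 amplitude = max(diff(range(x)), diff(range(y)))),
            class = "cycle_trace")
}

#' Signed area of a closed path
#'
#' Trapezoid (shoelace) integral of y dx around the path closed back to its
#' first point. A counter-clockwise loop yields a negative value under this
#' convention.
#'
#' @param x,y path coordinates in traversal order.
#' @return signed area.
#' @export
signed_area <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) return(0)
  xc <- c(x, x[1L]); yc <- c(y, y[1L])
  sum(0.5 * (yc[-1L] + yc[-length(yc)]) * diff(xc))
}

#' @export
print.cycle_trace <- function(x, ...) {
  cat("Adjustment-cycle trace\n")
  cat(sprintf("  %d ticks, signed area %.4g (%s), amplitude %.3g%%\n",
              nrow(x$path), x$signed_area, x$orientation, x$amplitude))
  invisible(x)
}
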