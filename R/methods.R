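#' @export
print.cascade_run <- function(x, ...) {
  m <- x$manifest
  cat("Cascade simulation run\n")
  cat(sprintf("  %d nodes, shock s=%.2f at tick %d (%d food nodes in epicenter)\n",
              length(x$net$nodes), m$shock, x$shock_tick,
              length(attr(x$epicenter, "food_nodes"))))
  cat(sprintf("  burn-in %d ticks (%s), post-shock %d ticks (%s)\n",
              m$burn_ticks, if (m$converged_burn) "converged" else "NOT converged",
              m$post_ticks, if (m$converged_post) "converged" else "NOT converged"))
  cat(sprintf("  seed %d, mode %s, config %s\n", m$seed, m$mode,
              m$config_checksum))
  invisible(x)
}

#' Summarise a cascade run
#'
#' Reports the pre-shock equilibrium (coefficients of variation of wages and
#' price indices at the last burn-in tick) and the post-shock outcome
#' (spatial-mean food-to-labor price ratio and per-capita consumption at the
#' final tick, against their pre-shock values).
#'
#' @param object a \code{cascade_run}.
#' @param ... unused.
#' @return a list of class \code{summary.cascade_run}.
#' @export
summary.cascade_run <- function(object, ...) {
  cv <- function(v) stats::sd(v) / mean(v)
  b <- object$shock_tick
  tt <- nrow(object$panel$w)
  out <- list(
    n_nodes = length(object$net$nodes),
    shock = object$manifest$shock,
    shock_tick = b,
    ticks = tt,
    unconverged = object$manifest$unconverged,
    baseline_cv_w = cv(object$panel$w[b, ]),
    baseline_cv_p = cv(object$panel$p[b, ]),
    baseline_cons = mean(object$panel$cons[b, ]),
    final_cons = mean(object$panel$cons[tt, ]),
    baseline_ratio = mean(object$panel$p_F[b, ] / object$panel$w[b, ]),
    final_ratio = mean(object$panel$p_F[tt, ] / object$panel$w[tt, ]),
    total_labor = sum(object$panel$L[tt, ])
  )
  class(out) <- "summary.cascade_run"
  out
}

#' @export
print.summary.cascade_run <- function(x, ...) {
  cat("Cascade run summary\n")
  cat(sprintf("  shock s=%.2f at tick %d of %d; %s\n", x$shock, x$shock_tick,
              x$ticks, if (x$unconverged) "UNCONVERGED" else "converged"))
  cat(sprintf("  pre-shock equilibrium: CV(w)=%.2e, CV(p)=%.2e\n",
              x$baseline_cv_w, x$baseline_cv_p))
  cat(sprintf("  food-to-labor price ratio: %.4f -> %.4f\n",
              x$baseline_ratio, x$final_ratio))
  cat(sprintf("  per-capita food consumption: %.4f -> %.4f\n",
              x$baseline_cons, x$final_cons))
  cat(sprintf("  total labor: %.2f\n", x$total_labor))
  invisible(x)
}

#' @export
as.data.frame.cascade_run <- function(x, ...) {
  tt <- nrow(x$panel$L); n <- ncol(x$panel$L)
  out <- data.frame(tick = rep(seq_len(tt), n),
                    node = rep(seq_len(n), each = tt))
  for (v in names(x$panel)) out[[v]] <- as.vector(x$panel[[v]])
  out$phase <- ifelse(out$tick <= x$shock_tick, "burn_in", "post_shock")
  out
}

#' Plot a cascade run
#'
#' \code{type = "series"} draws the spatial-mean wage, food price and
#' per-capita consumption over time with the shock tick marked;
#' \code{type = "network"} draws the spatial layout with food producers,
#' non-food producers and the epicenter region.
#'
#' @param x a \code{cascade_run}.
#' @param type \code{"series"} or \code{"network"}.
#' @param ... passed to the underlying plot calls.
#' @return invisibly, \code{x}.
#' @export
plot.cascade_run <- function(x, type = c("series", "network"), ...) {
  type <- match.arg(type)
  if (type == "series") {
    tt <- nrow(x$panel$w)
    op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(op))
    for (v in c("w", "p_F", "cons")) {
      graphics::plot(seq_len(tt), rowMeans(x$panel[[v]]), type = "l",
                     xlab = "tick", ylab = v, ...)
      graphics::abline(v = x$shock_tick, lty = 2)
    }
  } else {
    food <- x$net$producer_type == "food"
    graphics::plot(x$net$coords, asp = 1, pch = ifelse(food, 19, 17),
                   col = ifelse(food, "darkgreen", "purple"),
                   xlab = "x", ylab = "y", ...)
    e <- x$net$edges
    graphics::segments(x$net$coords[e[, 1L], 1L], x$net$coords[e[, 1L], 2L],
                       x$net$coords[e[, 2L], 1L], x$net$coords[e[, 2L], 2L],
                       col = "grey80")
    graphics::points(x$net$coords[x$epicenter, , drop = FALSE], cex = 2.2,
                     col = "grey40")
    graphics::symbols(attr(x$epicenter, "center")[1L],
                      attr(x$epicenter, "center")[2L],
                      circles = attr(x$epicenter, "radius"), add = TRUE,
                      inches = FALSE, fg = "grey40")
  }
  invisible(x)
}

#' @export
plot.cycle_trace <- function(x, ...) {
  graphics::plot(x$path$ratio_pct, x$path$cons_pct, type = "l",
                 xlab = "food-to-labor price ratio change (%)",
                 ylab = "consumption per capita change (%)", ...)
  graphics::points(x$path$ratio_pct[1L], x$path$cons_pct[1L], pch = 19)
  invisible(x)
}

#' @export
plot.heat_bin_grid <- function(x, ...) {
  k <- dim(x)[3L]
  op <- graphics::par(mfrow = c(2, ceiling(k / 2)), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  zr <- range(x, na.rm = TRUE)
  for (i in seq_len(k)) {
    graphics::image(seq_len(dim(x)[1L]), seq_len(dim(x)[2L]), x[, , i],
                    zlim = zr, xlab = "distance bin", ylab = "density bin",
                    main = paste("tick", attr(x, "snapshot_ticks")[i]), ...)
  }
  invisible(x)
}
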