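## build a tiny fake cascade_run with prescribed panels, for metric unit tests
fake_run <- function(p_F, w, cons, net, epicenter, shock_tick, seed = 1L,
                     s = 0.8) {
  structure(list(
    panel = list(p_F = p_F, w = w, cons = cons, p = p_F, alpha = 0 * p_F + 0.5,
                 L = 0 * p_F + 100),
    net = net, epicenter = epicenter, shock_tick = shock_tick,
    scenario = cascade_scenario(),
    manifest = list(seed = seed, shock = s, unconverged = FALSE)
  ), class = "cascade_run")
}

test_that("indicators against the baseline itself are identically zero", {
  sc <- quick_scenario(n = 15L, t_max = 800L)
  sc$shock$s <- 0
  run <- run_cascade(sc)
  ind <- indicators(run, run)
  expect_true(all(ind$ratio_pct == 0))
  expect_true(all(ind$cons_pct == 0))
})

test_that("indicator arithmetic follows the ratio definitions", {
  net <- ring4()
  ep <- structure(1L, food_nodes = 1L, center = c(.3, .3), radius = .1)
  tmat <- function(v) matrix(v, nrow = 3, ncol = 4)
  base <- fake_run(tmat(1), tmat(1), tmat(0.25), net, ep, 1L)
  ## p_F doubles and w halves: the food-to-labor ratio quadruples
  shocked <- fake_run(tmat(2), tmat(0.5), tmat(0.25), net, ep, 1L)
  ind <- indicators(shocked, base)
  expect_equal(unique(as.vector(ind$ratio)), 4)
  expect_equal(unique(as.vector(ind$ratio_pct)), 300)
  ## alpha = 0.5, w = 1, p_F = 2 -> consumption 0.25 is the recorded panel
  expect_equal(unique(as.vector(ind$cons)), 0.25)
  ## mismatched pairing is rejected
  other <- fake_run(tmat(1), tmat(1), tmat(0.25), net, ep, 1L, seed = 2L)
  expect_error(indicators(shocked, other), "pairing")
})

test_that("heat bins average the field per distance-density cell", {
  set.seed(4)
  net <- generate_network(30, target_mean_degree = 4, seed = 4)
  ep <- select_epicenter(net, c(0.25, 0.25),
                         epicenter_radius(net, c(0.25, 0.25), 0.2))
  centroid <- colMeans(net$coords[ep, , drop = FALSE])
  d <- sqrt((net$coords[, 1] - centroid[1])^2 +
            (net$coords[, 2] - centroid[2])^2)
  d[ep] <- 0
  dn <- d / max(d)
  ## a monotone synthetic field equal to the normalized distance
  fld <- matrix(dn, nrow = 4, ncol = 30, byrow = TRUE)
  run <- fake_run(fld, fld * 0 + 1, fld, net, ep, 1L)
  base <- fake_run(fld * 0 + 1, fld * 0 + 1, fld * 0 + 1, net, ep, 1L)
  ind <- indicators(run, base)
  hb <- heat_bins(ind, value = "cons", n_dist_bins = 4L, n_dens_bins = 2L,
                  snapshot_ticks = c(2L, 4L))
  ## brute-force cell means
  db <- attr(hb, "dist_bin"); zb <- attr(hb, "dens_bin")
  for (i in 1:4) for (j in seq_len(dim(hb)[2])) {
    inb <- db == i & zb == j
    if (any(inb)) expect_equal(hb[i, j, 1], mean(dn[inb]), tolerance = 1e-12)
    else expect_true(is.na(hb[i, j, 1]))
  }
  ## epicenter members map to the first distance bin
  expect_true(all(db[ep] == 1L))
  ## farthest node maps to the last bin
  expect_equal(db[which.max(dn)], 4L)
  ## count-weighted mean over cells reproduces the global snapshot mean
  cnt <- attr(hb, "counts")
  expect_equal(sum(hb[, , 1] * cnt, na.rm = TRUE) / sum(cnt), mean(dn),
               tolerance = 1e-12)
  ## 1x1 binning is the grand mean
  hb1 <- heat_bins(ind, value = "cons", n_dist_bins = 1L, n_dens_bins = 1L,
                   snapshot_ticks = 2L)
  expect_equal(as.vector(hb1[1, 1, 1]), mean(dn), tolerance = 1e-12)
  expect_error(heat_bins(ind, n_dist_bins = 0L), "bin counts")
})

test_that("the signed area is negative for counter-clockwise loops", {
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  ## counter-clockwise circle
  expect_lt(signed_area(cos(th), sin(th)), 0)
  ## clockwise traversal flips the sign
  expect_gt(signed_area(cos(-th), sin(-th)), 0)
  ## magnitude approximates the enclosed area pi
  expect_equal(abs(signed_area(cos(th), sin(th))), pi, tolerance = 1e-3)
  expect_equal(signed_area(c(0, 1), c(0, 1)), 0)
})

test_that("a no-shock run gives a degenerate cycle of zero area", {
  sc <- quick_scenario(n = 15L, t_max = 800L)
  sc$shock$s <- 0
  run <- run_cascade(sc)
  ct <- cycle_trace(indicators(run, run))
  expect_equal(ct$signed_area, 0)
  expect_equal(ct$amplitude, 0)
})

test_that("sweep indicator summaries carry one row per run", {
  sc <- quick_scenario(n = 20L, t_max = 900L)
  sw <- sweep_cascade(sc, shock_levels = c(0.4, 0.8), n_networks = 2L)
  si <- sweep_indicators(sw)
  expect_equal(nrow(si), 4L)
  expect_true(all(c("network", "s", "mean_ratio_pct", "mean_cons_pct",
                    "peak_ratio_pct", "trough_cons_pct") %in% names(si)))
  ## shocks raise the affordability stress indicator on average
  expect_true(all(si$peak_ratio_pct > 0))
})
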