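test_that("generated networks match the configured producer split", {
  net <- generate_network(80, food_frac = 0.5, target_mean_degree = 8, seed = 7)
  expect_equal(sum(net$producer_type == "food"), 40)
  expect_equal(length(net$nodes), 80)
  net2 <- generate_network(30, food_frac = 0.3, target_mean_degree = 4, seed = 2)
  expect_equal(sum(net2$producer_type == "food"), floor(0.3 * 30))
})

test_that("minimal networks are forced connected by the MST augmentation", {
  net <- generate_network(2, food_frac = 0.5, target_mean_degree = 2, seed = 1)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(as.integer(net$edges), c(1L, 2L))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_network(20, seed = 11)
  b <- generate_network(20, seed = 11)
  expect_identical(a$coords, b$coords)
  expect_identical(a$edges, b$edges)
  expect_identical(a$producer_type, b$producer_type)
  c <- generate_network(20, seed = 12)
  expect_false(identical(a$coords, c$coords))
})

test_that("every generated network is connected and hits the degree target", {
  for (seed in 1:8) {
    net <- generate_network(40, target_mean_degree = 6, seed = seed)
    expect_true(vrankcascade:::network_connected(net))
    expect_lt(abs(mean(net$degree$union) - 6), 1)
  }
})

test_that("degenerate generator configurations are rejected by name", {
  expect_error(generate_network(1), "n_nodes")
  expect_error(generate_network(10, food_frac = 0), "food_frac")
  expect_error(generate_network(10, food_frac = 1), "food_frac")
  expect_error(generate_network(10, target_mean_degree = 1), "target_mean_degree")
})

test_that("epicenter selection returns nodes within the radius", {
  net <- generate_network(80, seed = 3)
  ## a node's own location with a hair of radius selects it (and co-located)
  i <- which(net$producer_type == "food")[1]
  ep <- select_epicenter(net, center = net$coords[i, ], radius = 1e-9)
  expect_true(i %in% ep)
  ## the unit-square diameter bound captures everything
  ep_all <- select_epicenter(net, center = c(0, 0), radius = sqrt(2) + 1e-9)
  expect_equal(sort(as.integer(ep_all)), 1:80)
  ## brute-force count at the fraction-derived radius
  r <- epicenter_radius(net, c(0.25, 0.25), frac = 0.2)
  ep20 <- select_epicenter(net, c(0.25, 0.25), r)
  dd <- sqrt(colSums((t(net$coords) - c(0.25, 0.25))^2))
  expect_equal(sort(as.integer(ep20)), sort(which(dd <= r)))
  expect_gte(length(ep20), ceiling(0.2 * 80))
  expect_true(length(attr(ep20, "food_nodes")) > 0)
})

test_that("an epicenter without food producers is a scenario error", {
  net <- manual_network(rbind(c(.1, .1), c(.2, .1), c(.9, .9)),
                        rbind(c(1L, 2L), c(2L, 3L)),
                        c("nonfood", "nonfood", "food"))
  expect_error(select_epicenter(net, c(0.15, 0.1), 0.2), "food")
  expect_error(select_epicenter(net, c(5, 5), 0.1), "no nodes")
})

test_that("normalized distances are fractions of the farthest neighbor", {
  net <- manual_network(rbind(c(0, 0), c(1, 0), c(2, 0), c(4, 0)),
                        rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                        c("food", "nonfood", "nonfood", "nonfood"))
  nd <- normalized_distances(net, 1)
  expect_equal(unname(nd), c(0.25, 0.5, 1.0))
  ## scale invariance
  net2 <- manual_network(rbind(c(0, 0), c(3, 0), c(6, 0), c(12, 0)),
                         rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                         c("food", "nonfood", "nonfood", "nonfood"))
  expect_equal(unname(normalized_distances(net2, 1)), unname(nd))
  ## single neighbor maps to exactly 1
  expect_equal(unname(normalized_distances(net, 4)), 1)
  ## isolated node errors
  net3 <- manual_network(rbind(c(0, 0), c(1, 0), c(0, 1)),
                         rbind(c(1L, 2L)), c("food", "nonfood", "nonfood"))
  expect_error(normalized_distances(net3, 3), "isolated")
})

test_that("network tables survive a write/read round trip", {
  net <- generate_network(15, target_mean_degree = 4, seed = 5)
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  write_network(net, nf, ef)
  back <- read_network(nf, ef)
  expect_equal(back$edges, net$edges, ignore_attr = TRUE)
  expect_equal(as.character(back$producer_type), as.character(net$producer_type))
  expect_equal(back$coords, net$coords, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(c(nf, ef))
})
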