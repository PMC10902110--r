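test_that("graph construction follows the conductance rule and adjacency", {
  # 1x2 uniform resistance 1: single edge of conductance 1
  g <- build_raster_graph(uniform_raster(1, 2), 4)
  expect_equal(length(g$a), 1)
  expect_equal(g$g, 1)

  # diagonal pair at resistance 10: g = 1 / (10 * sqrt(2))
  r <- grid_raster(matrix(c(10, 100, 100, 10), 2, 2))
  g8 <- build_raster_graph(r, 8)
  diag_edges <- abs(g8$a - g8$b) == 3 # cells 1 and 4 column-major
  expect_true(any(diag_edges))
  idx <- which(g8$a == 1 & g8$b == 4)
  expect_equal(g8$g[idx], 1 / (10 * sqrt(2)), tolerance = 1e-12)

  # 3x3: 12 orthogonal + 8 diagonal edges; 4-neighbourhood drops diagonals
  expect_equal(length(build_raster_graph(uniform_raster(3, 3), 8)$a), 20)
  expect_equal(length(build_raster_graph(uniform_raster(3, 3), 4)$a), 12)

  # mixed-resistance orthogonal edge: mean-resistance coupling
  r2 <- grid_raster(matrix(c(1, 100), 1, 2))
  expect_equal(build_raster_graph(r2, 4)$g, 1 / ((1 + 100) / 2))

  expect_error(build_raster_graph(grid_raster(matrix(c(1, 0), 1, 2))),
               "finite and > 0")
})

test_that("series and parallel circuits solve to closed-form values", {
  # two cells, one unit edge: Ohm's law
  g <- build_raster_graph(uniform_raster(1, 2), 4)
  s <- solve_pair(g, 1, 2)
  expect_equal(s$potentials, c(1, 0))
  expect_equal(pair_current_density(g, s), c(1, 1))
  expect_equal(effective_resistance(g, 1, 2), 1)

  # 1x3 unit chain: series resistance 2, midpoint at half potential,
  # all current through the middle
  g3 <- build_raster_graph(uniform_raster(1, 3), 4)
  s3 <- solve_pair(g3, 1, 3)
  expect_equal(effective_resistance(g3, 1, 3), 2, tolerance = 1e-10)
  expect_equal(s3$potentials[2], s3$potentials[1] / 2, tolerance = 1e-10)
  expect_equal(pair_current_density(g3, s3), c(1, 1, 1), tolerance = 1e-10)

  # 2x2 square between opposite corners: two 2-edge paths in parallel,
  # Reff = 1, and the two off-terminal cells carry symmetric density
  g4 <- build_raster_graph(uniform_raster(2, 2), 4)
  expect_equal(effective_resistance(g4, 1, 4), 1, tolerance = 1e-10)
  d4 <- pair_current_density(g4, solve_pair(g4, 1, 4))
  expect_equal(d4[2], d4[3], tolerance = 1e-12)
  expect_equal(d4, oracle_density(g4, 1, 4), tolerance = 1e-8)
})

test_that("sparse solves match the dense pseudoinverse oracle on random grids", {
  skip_if_not_installed("MASS")
  cases <- list(c(5, 5, 8), c(10, 10, 4), c(10, 10, 8), c(8, 12, 8))
  for (k in seq_along(cases)) {
    nr <- cases[[k]][1]; nc <- cases[[k]][2]; nb <- cases[[k]][3]
    g <- build_raster_graph(random_resistance_raster(nr, nc, seed = 100 + k), nb)
    src <- 1; tgt <- g$n
    s <- solve_pair(g, src, tgt)
    expect_lt(max(abs(s$potentials - oracle_potentials(g, src, tgt))), 1e-8)
    expect_lt(max(abs(pair_current_density(g, s) - oracle_density(g, src, tgt))),
              1e-8)
    expect_equal(effective_resistance(g, src, tgt),
                 oracle_effective_resistance(g, src, tgt), tolerance = 1e-8)
  }
})

test_that("Kirchhoff conservation and source-target reciprocity hold", {
  g <- build_raster_graph(random_resistance_raster(9, 9, seed = 42), 8)
  src <- 5; tgt <- 77
  s <- solve_pair(g, src, tgt)
  # signed net flow at every node equals the injection vector
  v <- s$potentials
  flow <- g$g * (v[g$a] - v[g$b])
  net <- numeric(g$n)
  for (e in seq_along(g$a)) {
    net[g$a[e]] <- net[g$a[e]] + flow[e]
    net[g$b[e]] <- net[g$b[e]] - flow[e]
  }
  expected <- numeric(g$n); expected[src] <- 1; expected[tgt] <- -1
  expect_lt(max(abs(net - expected)), 1e-8)

  # swapping source and target leaves the density map unchanged
  d1 <- pair_current_density(g, s)
  d2 <- pair_current_density(g, solve_pair(g, tgt, src))
  expect_lt(max(abs(d1 - d2)), 1e-10)
})

test_that("resistance scaling changes Reff proportionally but not densities", {
  r <- random_resistance_raster(7, 7, seed = 8)
  g1 <- build_raster_graph(r, 8)
  r2 <- r; r2$data <- r$data * 5
  g2 <- build_raster_graph(r2, 8)
  expect_equal(effective_resistance(g2, 1, 49),
               5 * effective_resistance(g1, 1, 49), tolerance = 1e-10)
  d1 <- pair_current_density(g1, solve_pair(g1, 1, 49))
  d2 <- pair_current_density(g2, solve_pair(g2, 1, 49))
  expect_lt(max(abs(d1 - d2)), 1e-10)
})

test_that("disconnected terminals fail loudly", {
  # two components: a zero-conductance gap is impossible by construction,
  # so emulate disconnection with a 1-row raster cut by enormous resistance
  g <- build_raster_graph(uniform_raster(1, 2), 4)
  expect_error(solve_pair(g, 1, 1), "must differ")
  # a graph made of one cell cannot pair
  g1 <- build_raster_graph(uniform_raster(2, 1), 4)
  expect_silent(solve_pair(g1, 1, 2))
})

test_that("mean current map averages pairs and records its transform", {
  r <- uniform_raster(6, 6)
  g <- build_raster_graph(r, 8)
  nodes <- data.frame(row = c(1, 6), col = c(1, 6))
  nodes$x <- (nodes$col - 0.5) * 10; nodes$y <- (6 - nodes$row + 0.5) * 10

  # 2 nodes: the map is that single pair's density map
  cm_raw <- mean_current_map(g, nodes, log10_floor = NULL)
  expect_equal(attr(cm_raw, "n_pairs"), 1)
  s <- solve_pair(g, 1, 36)
  expect_equal(as.vector(cm_raw$data), pair_current_density(g, s),
               tolerance = 1e-10)
  expect_false(attr(cm_raw, "log10_applied"))

  # log10 default records floor and applies the transform
  cm_log <- mean_current_map(g, nodes)
  expect_true(attr(cm_log, "log10_applied"))
  expect_equal(as.vector(cm_log$data),
               log10(pmax(pair_current_density(g, s), 1e-12)),
               tolerance = 1e-10)

  # node order invariance: shuffled node table gives the identical map
  nodes4 <- data.frame(row = c(1, 1, 6, 6), col = c(1, 6, 1, 6))
  nodes4$x <- (nodes4$col - 0.5) * 10; nodes4$y <- (6 - nodes4$row + 0.5) * 10
  m1 <- mean_current_map(g, nodes4, log10_floor = NULL)
  m2 <- mean_current_map(g, nodes4[c(3, 1, 4, 2), ], log10_floor = NULL)
  expect_equal(attr(m1, "n_pairs"), 6)
  expect_equal(m1$data, m2$data, tolerance = 1e-12)
})

test_that("nearest-neighbour pair mode uses fewer pairs than all-pairs", {
  r <- uniform_raster(8, 8)
  g <- build_raster_graph(r, 8)
  set.seed(5)
  nodes <- place_perimeter_nodes(r, 12, seed = 5)
  m_all <- mean_current_map(g, nodes, log10_floor = NULL, pair_mode = "all")
  m_nn <- mean_current_map(g, nodes, log10_floor = NULL, pair_mode = "nearest")
  expect_equal(attr(m_all, "n_pairs"), choose(12, 2))
  expect_lt(attr(m_nn, "n_pairs"), choose(12, 2))
  expect_gte(attr(m_nn, "n_pairs"), 12 * 8 / 2 / 2) # at least half the directed lists
})

test_that("raising one corridor's resistance reroutes current to the other", {
  base <- two_corridor_graph(r_top = 10, r_bottom = 10)
  raised <- two_corridor_graph(r_top = 100, r_bottom = 10)
  d0 <- pair_current_density(base$graph, solve_pair(base$graph, base$source, base$target))
  d1 <- pair_current_density(raised$graph, solve_pair(raised$graph, raised$source, raised$target))
  expect_lt(sum(d1[base$top]), sum(d0[base$top]))
  expect_gt(sum(d1[base$bottom]), sum(d0[base$bottom]))
})
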