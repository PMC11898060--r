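test_that("find_minima resolves single and double wells and flat grids", {
  ax <- pucker_axes(40, 20)
  x <- glycofel:::axis_nodes(ax[[1]]); y <- glycofel:::axis_nodes(ax[[2]])
  # single Gaussian well
  U1 <- outer(x, y, function(a, b) -5 * exp(-((a - pi)^2 + (b - 1.5)^2) / 0.3))
  m1 <- find_minima(as_fes_grid(U1, ax))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$phi, x[which.min(abs(x - pi))], tolerance = 1e-9)
  # double well, deeper one first
  pot <- double_well_potential(5)
  U2 <- outer(x, y, function(a, b) potential_eval(pot, a, b))
  U2 <- U2 + outer(rep(1, 40), 0.3 * (y - 1))  # tilt so depths differ
  m2 <- find_minima(as_fes_grid(U2, ax), depth_threshold = 0.5)
  expect_equal(nrow(m2), 2)
  expect_lt(m2$free_energy[1], m2$free_energy[2])
  expect_true(is.infinite(m2$depth[1]))
  # constant grid has no strict minima
  expect_equal(nrow(find_minima(as_fes_grid(matrix(1, 40, 20), ax,
                                            shift = FALSE))), 0)
})

test_that("basin depth filtering removes shallow satellites", {
  ax <- list(grid_axis("phi", 0, 2 * pi, 30, periodic = TRUE),
             grid_axis("theta", 0, pi, 15))
  x <- glycofel:::axis_nodes(ax[[1]]); y <- glycofel:::axis_nodes(ax[[2]])
  U <- outer(x, y, function(a, b) {
    -6 * exp(-((a - 2)^2 + (b - 1.5)^2) / 0.2) -
      0.4 * exp(-((a - 4.5)^2 + (b - 1.5)^2) / 0.05)
  })
  deep <- find_minima(as_fes_grid(U, ax), depth_threshold = 1)
  all_m <- find_minima(as_fes_grid(U, ax), depth_threshold = 0)
  expect_gte(nrow(all_m), 2)
  expect_equal(nrow(deep), 1)
})

test_that("minimax optimality matches the Floyd-Warshall oracle", {
  set.seed(21)
  for (r in 1:40) {
    n1 <- sample(4:6, 1); n2 <- sample(4:6, 1)
    per1 <- r %% 2 == 0
    fes <- random_fes(n1, n2, per1 = per1, seed = 100 + r)
    s <- c(sample(n1, 1), sample(n2, 1))
    e <- c(sample(n1, 1), sample(n2, 1))
    path <- find_mfep(fes, s, e)
    got <- max(path$free_energy)
    want <- oracle_minimax(fes$values, per1, FALSE,
                           glycofel:::.node_id(s, n1),
                           glycofel:::.node_id(e, n1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("paths are adjacency-valid and reverse symmetrically", {
  fes <- random_fes(6, 6, seed = 5)
  p1 <- find_mfep(fes, c(1, 1), c(6, 6))
  p2 <- find_mfep(fes, c(6, 6), c(1, 1))
  expect_equal(max(p1$free_energy), max(p2$free_energy))
  expect_equal(p1$i, rev(p2$i))
  expect_equal(p1$j, rev(p2$j))
  # consecutive nodes are 8-neighbors
  expect_true(all(abs(diff(p1$i)) <= 1 & abs(diff(p1$j)) <= 1))
  expect_true(all(diff(p1$arc_length) > 0))
})

test_that("the path wraps through a periodic corridor", {
  n1 <- 24; n2 <- 9
  ax <- list(grid_axis("phi", 0, 2 * pi, n1, periodic = TRUE),
             grid_axis("theta", 0, pi, n2))
  vals <- matrix(10, n1, n2)
  vals[c(1, 2, n1 - 1, n1), ] <- 1     # low corridor across the seam only
  vals[2, 5] <- 0                       # start basin
  vals[n1 - 1, 5] <- 0.5                # end basin
  fes <- as_fes_grid(vals, ax, shift = FALSE)
  path <- find_mfep(fes, c(2, 5), c(n1 - 1, 5))
  expect_lt(max(path$free_energy), 2)   # never climbs the 10 kcal/mol wall
  expect_true(all(path$i %in% c(1, 2, n1 - 1, n1)))  # stays in the corridor
  expect_lt(nrow(path), 8)              # wraps instead of circling the long way
})

test_that("degenerate endpoints and bad nodes are handled", {
  fes <- random_fes(5, 5, seed = 2)
  p <- find_mfep(fes, c(3, 3), c(3, 3))
  expect_equal(nrow(p), 1)
  expect_equal(barrier_and_reaction_energy(p)$dg_activation, 0)
  expect_error(find_mfep(fes, c(0, 1), c(3, 3)), "outside")
})

test_that("barrier and reaction energies read off the profile", {
  p1 <- tibble::tibble(free_energy = c(0, 1, 2, 3))
  b1 <- barrier_and_reaction_energy(p1)
  expect_equal(b1$dg_activation, 3)
  expect_equal(b1$dg_reaction, 3)
  expect_equal(b1$ts_step, 4)
  p2 <- tibble::tibble(free_energy = c(0, 5, -3))
  b2 <- barrier_and_reaction_energy(p2)
  expect_equal(b2$dg_activation, 5)
  expect_equal(b2$dg_reaction, -3)
  expect_equal(b2$ts_step, 2)
})

test_that("activation energy is non-negative and bounds the reaction energy", {
  for (r in 1:20) {
    fes <- random_fes(6, 5, seed = 300 + r)
    p <- find_mfep(fes, c(1, 1), c(6, 5))
    b <- barrier_and_reaction_energy(p)
    expect_gte(b$dg_activation, 0)
    if (b$dg_reaction >= 0) expect_gte(b$dg_activation, b$dg_reaction)
  }
})

test_that("observables bin correctly along the path", {
  fes <- random_fes(10, 8, seed = 4)
  path <- find_mfep(fes, c(1, 1), c(10, 8))
  # constant observable -> constant profile in populated bins
  obs <- tibble::tibble(phi = path$phi, theta = path$theta, d = 1.5)
  prof <- profile_along_path(path, obs, bin_width = 0.3)
  expect_true(all(prof$d[prof$n > 0] == 1.5))
  expect_true(all(is.na(prof$d[prof$n == 0])))
  # observable linear in arc length -> bin means are the data means per bin
  obs2 <- tibble::tibble(phi = path$phi, theta = path$theta,
                         d = 2 * path$arc_length)
  prof2 <- profile_along_path(path, obs2, bin_width = 0.2)
  breaks <- seq(0, max(path$arc_length) + 0.2, by = 0.2)
  bins <- findInterval(path$arc_length, breaks, rightmost.closed = TRUE)
  want <- tapply(2 * path$arc_length, bins, mean)
  expect_equal(prof2$d[prof2$n > 0], as.vector(want), tolerance = 1e-12)
  expect_error(profile_along_path(path, obs, bin_width = 0), "positive")
})
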