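axes_small <- pucker_axes(36, 18)

test_that("an empty series reconstructs a uniformly zero surface", {
  h <- synthetic_hills_example(50)[0, ]
  fes <- reconstruct_fes(h, axes_small)
  expect_true(all(fes$values == 0))
})

test_that("a single tempered hill scales by gamma/(gamma-1)", {
  # hill centred exactly on a grid node (phi node 19, theta node 9)
  h <- tibble::tibble(time = 1, phi = pi, theta = 8 * pi / 17,
                      sigma_phi = 0.1, sigma_theta = 0.1,
                      height = 1, biasf = 15)
  fes <- reconstruct_fes(h, axes_small)
  # after the min-shift, far field sits (15/14)*1 kcal/mol above the center
  ic <- which.min(abs(fes$x - pi)); jc <- which.min(abs(fes$y - 8 * pi / 17))
  far <- fes$values[1, 18]  # corner, many sigma away
  expect_equal(far - fes$values[ic, jc], 15 / 14, tolerance = 1e-6)
  # prescaled dialect drops the factor
  fes2 <- reconstruct_fes(h, axes_small, dialect = "prescaled")
  expect_equal(max(fes2$values), max(fes$values) * 14 / 15, tolerance = 1e-9)
})

test_that("reconstruction matches the brute-force summation oracle", {
  h <- synthetic_hills_example(50, seed = 7)
  fes <- reconstruct_fes(h, axes_small)
  expect_lt(max(abs(fes$values - oracle_fes(h, axes_small))), 1e-10)
})

test_that("the surface is continuous across the periodic seam", {
  h <- tibble::tibble(time = 1, phi = 0.01, theta = 1.5,
                      sigma_phi = 0.2, sigma_theta = 0.2,
                      height = 1, biasf = 15)
  gap <- function(n) {
    fes <- reconstruct_fes(h, pucker_axes(n, 18))
    jc <- which.min(abs(fes$y - 1.5))
    abs(fes$values[1, jc] - fes$values[n, jc])
  }
  # the seam gap is a discretization artifact shrinking ~ 1/n
  expect_lt(gap(288), gap(36) / 4)
  expect_lt(gap(1152), 0.005)
})

test_that("gamma validation matches the dialect", {
  h <- synthetic_hills_example(5)
  h$biasf <- NULL
  expect_error(reconstruct_fes(h, axes_small), "gamma")
  expect_silent(reconstruct_fes(h, axes_small, dialect = "prescaled"))
  expect_error(reconstruct_fes(h, axes_small, gamma = 1), "gamma")
})

test_that("gridded surfaces round-trip through the text format", {
  fes <- reconstruct_fes(synthetic_hills_example(20), axes_small)
  f <- withr::local_tempfile()
  write_fes(fes, f)
  fes2 <- read_fes(f)
  expect_equal(fes2$values, fes$values, tolerance = 1e-12)
  expect_equal(fes2$x, fes$x, tolerance = 1e-12)
  expect_true(fes2$axes[[1]]$periodic)
})

test_that("region free energy matches closed forms and a direct sum", {
  ax <- list(grid_axis("phi", 0, 2 * pi, 10, periodic = TRUE),
             grid_axis("theta", 0, pi, 10))
  dA <- glycofel:::axis_spacing(ax[[1]]) * glycofel:::axis_spacing(ax[[2]])
  kT <- 0.596
  # single node at F = 0 with unit area element
  ax_unit <- list(grid_axis("a", 0, 2, 3), grid_axis("b", 0, 2, 3))  # dA = 1
  fes1 <- as_fes_grid(matrix(5, 3, 3) - 5, ax_unit)
  m1 <- matrix(FALSE, 3, 3); m1[1, 1] <- TRUE
  expect_equal(region_free_energy(fes1, m1, kT), 0, tolerance = 1e-12)
  # two equal-area nodes at F = 0: -kT ln 2
  m2 <- m1; m2[2, 1] <- TRUE
  expect_equal(region_free_energy(fes1, m2, kT), -kT * log(2),
               tolerance = 1e-12)
  # random grid against an independent direct summation
  set.seed(5)
  vals <- matrix(stats::runif(100, 0, 8), 10, 10)
  fes <- as_fes_grid(vals, ax, shift = FALSE)
  mask <- matrix(stats::runif(100) < 0.4, 10, 10)
  direct <- -kT * log(sum(exp(-vals[mask] / kT)) * dA)
  expect_equal(region_free_energy(fes, mask, kT), direct, tolerance = 1e-12)
  expect_error(region_free_energy(fes, mask & FALSE, kT), "no grid nodes")
})

test_that("delta_g_rnr vanishes on a mirror-symmetric surface and flips sign", {
  # 18 theta nodes symmetric about the equator; boundary at 90 deg
  ax <- pucker_axes(12, 18)
  th <- glycofel:::axis_nodes(ax[[2]])
  vals <- outer(rep(1, 12), (th - pi / 2)^2)  # even in theta about pi/2
  fes <- as_fes_grid(vals, ax)
  expect_equal(delta_g_rnr(fes), 0, tolerance = 1e-10)
  # asymmetric surface: mirroring theta flips the sign exactly
  set.seed(9)
  vals2 <- matrix(stats::runif(12 * 18, 0, 5), 12, 18)
  f1 <- as_fes_grid(vals2, ax, shift = FALSE)
  f2 <- as_fes_grid(vals2[, 18:1], ax, shift = FALSE)
  expect_equal(delta_g_rnr(f1), -delta_g_rnr(f2), tolerance = 1e-10)
  expect_equal(delta_g_rnr(f1, mode = "minimum"),
               -delta_g_rnr(f2, mode = "minimum"), tolerance = 1e-10)
})

test_that("two-state surfaces give the closed-form difference in both modes", {
  ax <- list(grid_axis("phi", 0, 2 * pi, 8, periodic = TRUE),
             grid_axis("theta", 0, pi, 8))
  th <- glycofel:::axis_nodes(ax[[2]])
  vals <- outer(rep(1, 8), ifelse(th < pi / 2, 0, 2))
  fes <- as_fes_grid(vals, ax, shift = FALSE)
  expect_equal(delta_g_rnr(fes, kT = 0.596), -2, tolerance = 1e-12)
  expect_equal(delta_g_rnr(fes, mode = "minimum"), -2, tolerance = 1e-12)
})

test_that("tidy/glance expose the grid in long form", {
  fes <- reconstruct_fes(synthetic_hills_example(10), axes_small)
  td <- tidy(fes)
  expect_equal(nrow(td), 36 * 18)
  expect_named(td, c("i", "j", "phi", "theta", "free_energy"))
  expect_equal(min(td$free_energy), 0)
  g <- glance(fes)
  expect_equal(g$n_hills, 10)
})
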