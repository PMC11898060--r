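test_that("an isolated atom recovers the closed-form sphere area", {
  a <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.5)
  got <- shrake_rupley(a, probe = 1.4, n_points = 960)$area
  expect_equal(got, 4 * pi * 2.9^2, tolerance = 1e-12)  # no occluders: exact
})

test_that("a fully enclosed atom has zero accessible area", {
  tc <- make_toy_complex(mouth_half_angle = 0, n_shell = 500, shell_radius = 6)
  res <- shrake_rupley(tc)
  expect_equal(res$area[res$group == "substrate"], 0)
})

test_that("two-sphere areas match a high-resolution quadrature oracle", {
  for (sep in c(2.0, 3.0, 4.5)) {
    atoms <- tibble::tibble(x = c(0, sep), y = 0, z = 0,
                            radius = c(1.5, 1.7))
    got <- shrake_rupley(atoms, probe = 1.4, n_points = 960)$area
    want <- c(oracle_sasa_one(atoms, 1, probe = 1.4),
              oracle_sasa_one(atoms, 2, probe = 1.4))
    expect_lt(max(abs(got - want) / want), 0.01)
  }
})

test_that("occluders never increase another atom's area", {
  base <- tibble::tibble(x = c(0, 2.5), y = 0, z = 0, radius = 1.5)
  more <- dplyr::bind_rows(base,
                           tibble::tibble(x = 1.2, y = 2.2, z = 0, radius = 1.5))
  a0 <- shrake_rupley(base)$area
  a1 <- shrake_rupley(more)$area[1:2]
  expect_true(all(a1 <= a0 + 1e-9))
})

test_that("areas converge with the point count", {
  tc <- make_toy_complex(mouth_half_angle = 60, n_shell = 120, shell_radius = 6)
  a960 <- shrake_rupley(tc, n_points = 960)$area
  a4096 <- shrake_rupley(tc, n_points = 4096)$area
  tot960 <- sum(a960); tot4096 <- sum(a4096)
  expect_lt(abs(tot960 - tot4096) / tot4096, 0.005)
})

test_that("SPI is the substrate/pocket area ratio in full context", {
  tc <- make_toy_complex(mouth_half_angle = 60, n_shell = 240, shell_radius = 6)
  res <- spi(tc)
  full <- shrake_rupley(tc)
  expect_equal(res$sasa_sub, sum(full$area[full$group == "substrate"]))
  expect_equal(res$sasa_pkt, sum(full$area[full$group == "pocket"]))
  expect_equal(res$spi, res$sasa_sub / res$sasa_pkt)
  # two geometrically identical, well-separated clusters: SPI = 1
  cl <- tibble::tibble(x = c(0, 1.8), y = 0, z = 0, radius = 1.5)
  twin <- dplyr::bind_rows(dplyr::mutate(cl, group = "substrate"),
                           dplyr::mutate(cl, x = x + 50, group = "pocket"))
  expect_equal(spi(twin)$spi, 1, tolerance = 1e-12)
})

test_that("SPI matches an independent per-atom oracle on a small complex", {
  tc <- make_toy_complex(mouth_half_angle = 75, n_shell = 40, shell_radius = 6)
  got <- spi(tc, n_points = 960)
  areas <- vapply(seq_len(nrow(tc)), function(i)
    oracle_sasa_one(tc, i, probe = 1.4, n_theta = 300, n_phi = 300),
    numeric(1))
  want <- sum(areas[tc$group == "substrate"]) / sum(areas[tc$group == "pocket"])
  expect_equal(got$spi, want, tolerance = 0.02)
})

test_that("grouped multi-frame input returns per-frame SPI with a summary", {
  tc <- make_toy_complex(mouth_half_angle = 60, n_shell = 60, shell_radius = 6)
  frames <- dplyr::bind_rows(dplyr::mutate(tc, frame = 1),
                             dplyr::mutate(tc, frame = 2))
  out <- spi(frames)
  expect_equal(nrow(out), 2)
  expect_equal(out$spi[1], out$spi[2])
  expect_equal(attr(out, "summary")$spi_sd, 0)
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(spi(tibble::tibble(x = 0, y = 0, z = 0, radius = 1,
                                  group = "substrate")), "pocket")
  expect_error(shrake_rupley(tibble::tibble(x = 0, y = 0, z = 0, radius = -1)),
               "positive")
  expect_error(sphere_points(0), "at least one")
})

test_that("united-atom mode drops hydrogens and inflates radii", {
  atoms <- tibble::tibble(x = c(0, 1.1), y = 0, z = 0,
                          element = c("C", "H"))
  res <- shrake_rupley(atoms, hydrogens = "united")
  expect_equal(nrow(res), 1)
  expect_equal(res$radius, vdw_radius("C") + 0.1)
})
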