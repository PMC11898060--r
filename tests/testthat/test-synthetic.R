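test_that("identical seeds reproduce trajectories and hills bit for bit", {
  pot <- pucker_landscape(delta = -4)
  sp <- sampler_params(n_steps = 2000, seed = 5)
  s1 <- sample_wt_metad(pot, sp)
  s2 <- sample_wt_metad(pot, sp)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(as.data.frame(s1$hills), as.data.frame(s2$hills))
  s3 <- sample_wt_metad(pot, sampler_params(n_steps = 2000, seed = 6))
  expect_false(identical(s1$trajectory, s3$trajectory))
})

test_that("unbiased dynamics equilibrate to the Boltzmann marginal", {
  # single broad well; compare the binned theta-marginal of a long
  # trajectory with the analytic Boltzmann weight
  pot <- potential_spec(tibble::tibble(x0 = pi, y0 = 1.5, sx = 3, sy = 1.0,
                                       A = -20))
  sp <- sampler_params(n_steps = 100000, w0 = 0, seed = 3)
  sim <- sample_wt_metad(pot, sp, start = c(pi, 1.5))
  y <- sim$trajectory$theta[-(1:5000)]
  breaks <- seq(0, pi, length.out = 13)
  emp <- as.vector(table(cut(y, breaks))) / length(y)
  yy <- seq(0.0005, pi - 0.0005, by = 0.001)
  w <- exp(-potential_eval(pot, rep(pi, length(yy)), yy) / sp$kT)
  theo <- vapply(seq_len(12), function(b) {
    sum(w[yy >= breaks[b] & yy < breaks[b + 1]])
  }, numeric(1))
  theo <- theo / sum(theo)
  expect_lt(max(abs(emp - theo)), 0.03)
})

test_that("near-harmonic fluctuations satisfy equipartition", {
  # deep Gaussian well: curvature at the bottom A/sigma^2 acts as a spring
  # a broad, deep Gaussian well approximates a harmonic spring
  # k = A/sigma^2 near its bottom; sigma is chosen large so the quartic
  # correction (~1.5 kT / (k sigma^2)) and the Euler-Maruyama bias
  # (~ mobility * k * dt / 2) both stay well below the tolerance
  pot <- potential_spec(tibble::tibble(x0 = pi, y0 = 1.5, sx = 2.0, sy = 2.0,
                                       A = -80))
  sp <- sampler_params(n_steps = 200000, w0 = 0, friction = 600, seed = 8)
  sim <- sample_wt_metad(pot, sp, start = c(pi, 1.5))
  v <- stats::var(sim$trajectory$theta[-(1:5000)])
  k_spring <- 80 / 2.0^2
  expect_lt(abs(v - sp$kT / k_spring) / (sp$kT / k_spring), 0.05)
})

test_that("well-tempered heights decay as the bias fills the wells", {
  pot <- double_well_potential(5)
  sp <- sampler_params(n_steps = 30000, pace = 50, sigma = c(0.35, 0.35),
                       gamma = 8, seed = 42)
  sim <- sample_wt_metad(pot, sp)
  h <- sim$hills$height
  expect_equal(h[1], sp$w0, tolerance = 1e-9)      # first hill undamped
  expect_lt(mean(tail(h, 50)), mean(head(h, 50)))  # damping with filling
  expect_true(all(h > 0 & h <= sp$w0))
})

test_that("the stop rule caps deposition once the surface range is reached", {
  pot <- double_well_potential(3)
  sp <- sampler_params(n_steps = 40000, pace = 25, sigma = c(0.4, 0.4),
                       gamma = 10, stop_threshold = 4, seed = 1)
  sim <- sample_wt_metad(pot, sp)
  # hills stop well before the step cap allows (40000/25 = 1600 hills)
  expect_lt(nrow(sim$hills), 1000)
  fes <- reconstruct_fes(sim$hills, pucker_axes(48, 24), gamma = 10)
  expect_lt(max(fes$values), 8)  # range near the threshold, not far beyond
})

test_that("gamma and kT validation", {
  expect_error(sampler_params(gamma = 1), "gamma")
  expect_error(sampler_params(kT = 0), "positive")
})

test_that("a short run already recovers the double-well barrier roughly", {
  pot <- double_well_potential(5)
  sp <- sampler_params(n_steps = 25000, pace = 50, sigma = c(0.35, 0.35),
                       gamma = 8, seed = 42)
  sim <- sample_wt_metad(pot, sp)
  fes <- reconstruct_fes(sim$hills, pucker_axes(64, 32), gamma = 8)
  m <- find_minima(fes, depth_threshold = 1)
  expect_gte(nrow(m), 2)
  bar <- glance(find_mfep(fes, m[1, ], m[2, ]))$dg_activation
  expect_lt(abs(bar - pot$barrier), 1.0)
})

test_that("make_ring recovers the target pucker and stays classifiable under noise", {
  p <- cremer_pople(make_ring(0.55, 90, 210, noise = 0))
  expect_equal(c(p$Q, p$theta, p$phi), c(0.55, 90, 210), tolerance = 1e-6)
  # unbiased recovery of theta under small coordinate noise
  th <- vapply(1:200, function(s)
    cremer_pople(make_ring(0.55, 90, 210, noise = 0.01, seed = s))$theta,
    numeric(1))
  expect_lt(abs(mean(th) - 90), 0.5)
  # classification at a canonical reference is robust to that noise
  tab <- cp_conformers()
  e5 <- tab[tab$label == "E5", ]
  lab <- vapply(1:200, function(s) {
    classify_conformer(cremer_pople(
      make_ring(0.55, e5$theta_ref, e5$phi_ref, noise = 0.01, seed = s)))$label
  }, character(1))
  expect_gte(mean(lab == "E5"), 0.99)
})

test_that("toy complexes expose closed-form limits", {
  lone <- make_toy_complex(n_shell = 0)
  res <- shrake_rupley(lone)
  expect_equal(res$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  expect_error(make_toy_complex(shell_radius = 2), "too small")
  fr <- make_catalytic_toy(d1 = 1.0, d2 = 1.5)
  expect_equal(cv1(fr), -0.5, tolerance = 1e-12)
  expect_error(make_catalytic_toy(d1 = -1), "positive")
})
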