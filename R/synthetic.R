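# Synthetic ground-truth generators: analytic 2D potentials sampled by
# well-tempered metadynamics over overdamped Langevin dynamics, ring
# geometries at prescribed puckers, and toy complexes for SASA.

#' Analytic 2D potential on a periodic x bounded domain
#'
#' A sum of Gaussian wells/barriers
#' \eqn{U(x,y) = \sum_k A_k \exp(-\Delta x_k^2/2\sigma_{x,k}^2
#'                              - \Delta y_k^2/2\sigma_{y,k}^2)}
#' (negative `A` = well) on a domain that is periodic in `x` and bounded
#' (reflective) in `y` -- the topology of the puckering coordinates phi
#' and theta.
#'
#' @param terms tibble with columns `x0`, `y0`, `sx`, `sy`, `A`
#'   (kcal/mol).
#' @param xlim,ylim domain bounds; `x` spans one period.
#' @param cv_names names of the two coordinates.
#' @return a `potential_spec` object.
#' @export
potential_spec <- function(terms, xlim = c(0, 2 * pi), ylim = c(0, pi),
                           cv_names = c("phi", "theta")) {
  check_columns(terms, c("x0", "y0", "sx", "sy", "A"), "potential terms")
  if (any(terms$sx <= 0 | terms$sy <= 0)) abort("widths must be positive")
  structure(list(terms = as_tibble(terms), xlim = xlim, ylim = ylim,
                 cv_names = cv_names),
            class = "potential_spec")
}

#' Evaluate an analytic potential (and optionally its gradient)
#'
#' @param pot a [potential_spec()].
#' @param x,y coordinates (vectorized).
#' @param gradient also return the gradient components.
#' @return energies (kcal/mol), or a list `(U, dUdx, dUdy)`.
#' @export
potential_eval <- function(pot, x, y, gradient = FALSE) {
  period <- pot$xlim[2] - pot$xlim[1]
  U <- numeric(length(x))
  gx <- numeric(length(x)); gy <- numeric(length(x))
  for (k in seq_len(nrow(pot$terms))) {
    tr <- pot$terms[k, ]
    dx <- min_image(x, tr$x0, period)
    dy <- y - tr$y0
    g <- tr$A * exp(-dx^2 / (2 * tr$sx^2) - dy^2 / (2 * tr$sy^2))
    U <- U + g
    if (gradient) {
      gx <- gx - g * dx / tr$sx^2
      gy <- gy - g * dy / tr$sy^2
    }
  }
  if (gradient) list(U = U, dUdx = gx, dUdy = gy) else U
}

#' Symmetric double-well test potential with a prescribed barrier
#'
#' Two equal Gaussian wells at the same `x`, separated along `y`; the well
#' depth is solved numerically so the analytic barrier between the two
#' minima (along the inter-well line) equals `barrier` exactly.  Metadata
#' (`minima`, `saddle`, `barrier`) are attached for parameter-recovery
#' tests.
#'
#' @param barrier target barrier, kcal/mol.
#' @param centers_y the two well centres along y (radians).
#' @param sigma common Gaussian width (radians).
#' @return a `potential_spec` with `minima`/`saddle`/`barrier` fields.
#' @export
double_well_potential <- function(barrier = 5, centers_y = c(0.9, 2.2),
                                  sigma = 0.35) {
  x0 <- pi
  slice <- function(y, A) {
    A * (exp(-(y - centers_y[1])^2 / (2 * sigma^2)) +
           exp(-(y - centers_y[2])^2 / (2 * sigma^2)))
  }
  # with A = -1, find minima and intervening maximum along the slice
  m1 <- optimize(slice, interval = c(0, mean(centers_y)), A = -1, tol = 1e-10)
  m2 <- optimize(slice, interval = c(mean(centers_y), pi), A = -1, tol = 1e-10)
  sd <- optimize(slice, interval = c(m1$minimum, m2$minimum), A = -1,
                 maximum = TRUE, tol = 1e-10)
  unit_barrier <- sd$objective - max(m1$objective, m2$objective)
  A <- -barrier / unit_barrier
  pot <- potential_spec(
    tibble(x0 = x0, y0 = centers_y, sx = sigma, sy = sigma, A = A)
  )
  pot$minima <- tibble(x = x0, y = c(m1$minimum, m2$minimum))
  pot$minima$U <- potential_eval(pot, pot$minima$x, pot$minima$y)
  pot$saddle <- tibble(x = x0, y = sd$maximum,
                       U = potential_eval(pot, x0, sd$maximum))
  pot$barrier <- pot$saddle$U - min(pot$minima$U)
  pot
}

#' Two-basin puckering-sphere landscape with tunable asymmetry
#'
#' Mimics the topology of a pyranose puckering free-energy landscape: one
#' well at an E5-like northern position (phi = 300 deg, theta = 54.7 deg)
#' and one at a 1S3-like southern position (phi = 210 deg, theta = 100
#' deg).  The southern well is centred just south of the equator rather
#' than exactly on it: the canonical 1S3 point lies on the equator, and a
#' basin straddling the default partition boundary would split its
#' Boltzmann mass between both regions; in the enzyme the
#' transition-state boundary runs north of 1S3, so the basin is wholly
#' nonreactive.  `delta` sets the target north-minus-south well-bottom
#' free energy: negative favors the northern (reactive) basin, as in an
#' active wild-type-like enzyme; positive favors the southern basin, as
#' in a D74E-like inactive variant.
#'
#' @param delta north - south well depth difference, kcal/mol.
#' @param base mean well depth, kcal/mol.
#' @param sigma well width, radians.
#' @return a `potential_spec`.
#' @export
pucker_landscape <- function(delta = -4, base = 6, sigma = 0.45) {
  depth_n <- base - delta / 2
  depth_s <- base + delta / 2
  if (depth_n <= 0 || depth_s <= 0) abort("delta too large for the base depth")
  potential_spec(tibble(
    x0 = deg2rad(c(300, 210)),
    y0 = c(0.9553, deg2rad(100)),
    sx = sigma, sy = sigma,
    A = c(-depth_n, -depth_s)
  ))
}

#' Sampler parameters for well-tempered metadynamics
#'
#' Defaults follow the conditions of a well-tempered puckering run:
#' Gaussian height 0.75 kcal/mol and width 0.1 rad, bias factor 15,
#' deposition every 75 steps, stop once the implied free-energy range
#' reaches 14 kcal/mol.  `kT` = 0.596 kcal/mol is 300 K.  The overdamped
#' Langevin mobility is `dt/friction`; the defaults give a thermal step of
#' about 0.1 rad.
#'
#' @param kT thermal energy, kcal/mol.
#' @param friction friction coefficient (energy * step / rad^2).
#' @param dt time step.
#' @param n_steps maximum number of steps.
#' @param pace steps between hill depositions.
#' @param w0 initial hill height, kcal/mol.
#' @param sigma hill widths per CV, radians.
#' @param gamma well-tempered bias factor (> 1).
#' @param seed RNG seed (recorded in the output).
#' @param stop_threshold implied FES range that stops deposition, kcal/mol.
#' @return a `sampler_params` list.
#' @export
sampler_params <- function(kT = 0.596, friction = 120, dt = 1,
                           n_steps = 100000, pace = 75, w0 = 0.75,
                           sigma = c(0.1, 0.1), gamma = 15, seed = 1,
                           stop_threshold = 14) {
  if (gamma <= 1) abort("the well-tempered bias factor gamma must exceed 1")
  if (kT <= 0 || friction <= 0 || dt <= 0 || pace < 1 || w0 < 0) {
    abort("sampler parameters must be positive")
  }
  structure(list(kT = kT, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps), pace = as.integer(pace),
                 w0 = w0, sigma = rep_len(sigma, 2), gamma = gamma,
                 seed = seed, stop_threshold = stop_threshold),
            class = "sampler_params")
}

#' Well-tempered metadynamics sampling of an analytic potential
#'
#' Overdamped Langevin dynamics on the biased potential, with a Gaussian
#' hill of height \eqn{w_0 \exp(-V(s)/((\gamma-1)kT))} deposited at the
#' walker position every `pace` steps.  The x coordinate wraps
#' periodically; y reflects at the domain walls.  Deposition stops when
#' the bias-implied free-energy range
#' \eqn{\gamma/(\gamma-1)\,(\max V - \min V)} (checked on a coarse grid
#' every 20 hills) exceeds the stop threshold, or at the step cap.
#' Identical seeds give identical output.
#'
#' @param pot a [potential_spec()].
#' @param params a [sampler_params()].
#' @param start starting point `c(x, y)`; default the domain centre.
#' @return list with `trajectory` (tibble: step, CV columns) and `hills`
#'   (tibble in HILLS layout with `cv_names`/`periodic` attributes and the
#'   seed recorded as attribute `seed`).
#' @export
sample_wt_metad <- function(pot, params = sampler_params(), start = NULL) {
  kT <- params$kT
  mob <- params$dt / params$friction
  noise_sd <- sqrt(2 * kT * mob)
  period <- pot$xlim[2] - pot$xlim[1]
  ylim <- pot$ylim
  if (is.null(start)) start <- c(mean(pot$xlim), mean(ylim))

  set.seed(params$seed)
  n <- params$n_steps
  max_hills <- n %/% params$pace + 1L
  hx <- numeric(max_hills); hy <- numeric(max_hills)
  hw <- numeric(max_hills); ht <- numeric(max_hills)
  nh <- 0L
  sx2 <- params$sigma[1]^2; sy2 <- params$sigma[2]^2
  cfac <- params$gamma / (params$gamma - 1)

  # coarse grid for the stop rule
  gxs <- pot$xlim[1] + period * (0:31) / 32
  gys <- seq(ylim[1], ylim[2], length.out = 17)
  gg <- expand.grid(x = gxs, y = gys)

  bias_and_grad <- function(x, y) {
    if (nh == 0L) return(c(0, 0, 0))
    dx <- min_image(x, hx[1:nh], period)
    dy <- y - hy[1:nh]
    g <- hw[1:nh] * exp(-dx^2 / (2 * sx2) - dy^2 / (2 * sy2))
    c(sum(g), -sum(g * dx) / sx2, -sum(g * dy) / sy2)
  }

  traj_x <- numeric(n); traj_y <- numeric(n)
  x <- start[1]; y <- start[2]
  stopped <- FALSE
  for (t in seq_len(n)) {
    u <- potential_eval(pot, x, y, gradient = TRUE)
    b <- bias_and_grad(x, y)
    x <- x - mob * (u$dUdx + b[2]) + noise_sd * rnorm(1)
    y <- y - mob * (u$dUdy + b[3]) + noise_sd * rnorm(1)
    x <- pot$xlim[1] + (x - pot$xlim[1]) %% period
    while (y < ylim[1] || y > ylim[2]) {
      if (y < ylim[1]) y <- 2 * ylim[1] - y
      if (y > ylim[2]) y <- 2 * ylim[2] - y
    }
    traj_x[t] <- x; traj_y[t] <- y

    if (!stopped && params$w0 > 0 && t %% params$pace == 0) {
      v_here <- bias_and_grad(x, y)[1]
      nh <- nh + 1L
      hx[nh] <- x; hy[nh] <- y
      hw[nh] <- params$w0 * exp(-v_here / ((params$gamma - 1) * kT))
      ht[nh] <- t * params$dt
      if (nh %% 20L == 0L) {
        dxg <- outer(gg$x, hx[1:nh], function(a, b) min_image(a, b, period))
        dyg <- outer(gg$y, hy[1:nh], `-`)
        Vg <- as.vector(exp(-dxg^2 / (2 * sx2) - dyg^2 / (2 * sy2)) %*% hw[1:nh])
        if (cfac * (max(Vg) - min(Vg)) >= params$stop_threshold) stopped <- TRUE
      }
    }
  }

  hills <- tibble(
    time = ht[seq_len(nh)],
    !!pot$cv_names[1] := hx[seq_len(nh)],
    !!pot$cv_names[2] := hy[seq_len(nh)],
    !!paste0("sigma_", pot$cv_names[1]) := params$sigma[1],
    !!paste0("sigma_", pot$cv_names[2]) := params$sigma[2],
    height = hw[seq_len(nh)],
    biasf = params$gamma
  )
  attr(hills, "cv_names") <- pot$cv_names
  periodic <- list(pot$xlim, NULL)
  names(periodic) <- pot$cv_names
  attr(hills, "periodic") <- periodic
  attr(hills, "seed") <- params$seed

  traj <- tibble(step = seq_len(n),
                 !!pot$cv_names[1] := traj_x,
                 !!pot$cv_names[2] := traj_y)
  list(trajectory = traj, hills = hills)
}

#' Ring geometry at a prescribed pucker, with optional noise
#'
#' Builds the exact inverse-Cremer-Pople geometry and adds isotropic
#' Gaussian coordinate noise.  With `noise = 0` the forward map recovers
#' the target to better than 1e-6.
#'
#' @param Q,theta,phi target puckering coordinates (degrees).
#' @param bond_length mean ring bond length, Angstrom.
#' @param noise coordinate noise standard deviation, Angstrom.
#' @param seed RNG seed (only used when `noise > 0`).
#' @return ring geometry tibble.
#' @export
make_ring <- function(Q = 0.55, theta = 90, phi = 210, bond_length = 1.54,
                      noise = 0, seed = NULL) {
  ring <- invert_cremer_pople(Q, theta, phi, bond_length = bond_length)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    ring$x <- ring$x + rnorm(6, sd = noise)
    ring$y <- ring$y + rnorm(6, sd = noise)
    ring$z <- ring$z + rnorm(6, sd = noise)
  }
  ring
}

#' Toy ligand-in-shell complex for SASA tests
#'
#' A ligand atom cluster at the origin surrounded by a spherical shell of
#' pocket atoms with an open mouth (a polar cap of half-angle
#' `mouth_half_angle` left empty).  `mouth_half_angle = 0` closes the
#' shell; `n_shell = 0` removes it.
#'
#' @param n_shell number of shell atoms.
#' @param shell_radius shell radius, Angstrom.
#' @param mouth_half_angle opening half-angle, degrees.
#' @param ligand_radius,shell_atom_radius atom radii, Angstrom.
#' @param n_ligand ligand atoms (1 = single sphere at the origin; more are
#'   placed on a small tetrahedral cluster).
#' @return atom tibble with `x`, `y`, `z`, `radius`, `group`.
#' @export
make_toy_complex <- function(n_shell = 240, shell_radius = 6,
                             mouth_half_angle = 60, ligand_radius = 1.7,
                             shell_atom_radius = 1.7, n_ligand = 1) {
  if (shell_radius <= 2 * max(ligand_radius, shell_atom_radius)) {
    abort("shell radius too small: shell would intersect the ligand")
  }
  lig_off <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                   c(-1, -1, 1)) * 0.9
  lig <- lig_off[seq_len(min(n_ligand, 5)), , drop = FALSE]
  atoms <- tibble(x = lig[, 1], y = lig[, 2], z = lig[, 3],
                  radius = ligand_radius, group = "substrate")
  if (n_shell > 0) {
    pts <- sphere_points(n_shell)
    keep <- pts[, 3] < cos(deg2rad(mouth_half_angle))  # mouth at +z pole
    pts <- pts[keep, , drop = FALSE] * shell_radius
    atoms <- bind_rows(atoms, tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                     radius = shell_atom_radius,
                                     group = "pocket"))
  }
  atoms
}

#' Catalytic-atom arrangement with prescribed reaction distances
#'
#' Places the acid carboxylate pair, proton, glycosidic oxygen, anomeric
#' carbon and nucleophile pair so that d1-d4 take the requested values
#' exactly, giving closed-form CV1 = d1 - d2 and CV2 = d3 - d4.
#'
#' @param d1 acid-pair midpoint to proton distance, Angstrom.
#' @param d2 proton to glycosidic oxygen distance.
#' @param d3 glycosidic oxygen to anomeric carbon distance.
#' @param d4 anomeric carbon to nucleophile-pair midpoint distance.
#' @param pair_sep separation of each carboxylate oxygen pair.
#' @return catalytic frame tibble (`role`, `x`, `y`, `z`).
#' @export
make_catalytic_toy <- function(d1 = 1.0, d2 = 1.5, d3 = 1.5, d4 = 3.0,
                               pair_sep = 2.2) {
  if (any(c(d1, d2, d3, d4) <= 0)) abort("distances must be positive")
  h <- pair_sep / 2
  og <- c(d1 + d2, 0, 0)
  c1 <- og + c(0, d3, 0)
  nuc_mid <- c1 + c(0, d4, 0)
  tibble(
    role = c("acid_o1", "acid_o2", "o_a", "h_a", "o_g", "c1p",
             "nuc_o1", "nuc_o2", "o_n", "o_ring"),
    x = c(0, 0, 0, d1, og[1], c1[1], nuc_mid[1], nuc_mid[1], nuc_mid[1],
          c1[1] + 1.01),
    y = c(h, -h, h, 0, og[2], c1[2], nuc_mid[2], nuc_mid[2], nuc_mid[2],
          c1[2] - 1.01),
    z = c(0, 0, 0, 0, 0, 0, h, -h, h, 0)
  )
}
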