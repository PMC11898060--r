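# Independent oracles used across the suite.  Each deliberately uses a
# different algorithm than the implementation it checks.

# Brute-force Gaussian summation of a hills series on a grid: plain double
# loop over nodes, no separability trick.
oracle_fes <- function(hills, axes, gamma = hills$biasf[1]) {
  nm <- c(axes[[1]]$name, axes[[2]]$name)
  x <- glycofel:::axis_nodes(axes[[1]])
  y <- glycofel:::axis_nodes(axes[[2]])
  V <- matrix(0, length(x), length(y))
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      v <- 0
      for (k in seq_len(nrow(hills))) {
        dx <- x[i] - hills[[nm[1]]][k]
        if (axes[[1]]$periodic) {
          p <- axes[[1]]$max - axes[[1]]$min
          dx <- dx - p * round(dx / p)
        }
        dy <- y[j] - hills[[nm[2]]][k]
        if (axes[[2]]$periodic) {
          p <- axes[[2]]$max - axes[[2]]$min
          dy <- dy - p * round(dy / p)
        }
        v <- v + hills$height[k] *
          exp(-dx^2 / (2 * hills[[paste0("sigma_", nm[1])]][k]^2) -
                dy^2 / (2 * hills[[paste0("sigma_", nm[2])]][k]^2))
      }
      V[i, j] <- v
    }
  }
  F <- -(gamma / (gamma - 1)) * V
  F - min(F)
}

# Exact minimax (bottleneck) value between two nodes by Floyd-Warshall
# closure over all paths: D[u,v] = min over paths of max node energy.
oracle_minimax <- function(F, per1, per2, s, e) {
  n1 <- nrow(F); n2 <- ncol(F)
  n <- n1 * n2
  Fv <- as.vector(F)
  D <- matrix(Inf, n, n)
  diag(D) <- Fv
  for (j in seq_len(n2)) {
    for (i in seq_len(n1)) {
      v <- i + (j - 1) * n1
      nb <- glycofel:::.grid_neighbors(i, j, n1, n2, per1, per2)
      u <- nb[, 1] + (nb[, 2] - 1) * n1
      D[v, u] <- pmax(Fv[v], Fv[u])
    }
  }
  for (k in seq_len(n)) {
    M <- pmax(matrix(D[, k], n, n), matrix(D[k, ], n, n, byrow = TRUE))
    D <- pmin(D, M)
  }
  D[s, e]
}

# High-resolution numeric SASA for one atom amid occluders: latitude x
# longitude quadrature with sin(theta) weights (independent of the
# Fibonacci point construction).
oracle_sasa_one <- function(atoms, which_atom, probe, n_theta = 1000,
                            n_phi = 1000) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rexp <- atoms$radius + probe
  i <- which_atom
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  wt <- sin(th) * (pi / n_theta) * (2 * pi / n_phi)
  acc <- 0
  others <- setdiff(seq_len(nrow(atoms)), i)
  for (t in seq_along(th)) {
    px <- xyz[i, 1] + rexp[i] * sin(th[t]) * cos(ph)
    py <- xyz[i, 2] + rexp[i] * sin(th[t]) * sin(ph)
    pz <- xyz[i, 3] + rexp[i] * cos(th[t])
    free <- rep(TRUE, n_phi)
    for (k in others) {
      free <- free & ((px - xyz[k, 1])^2 + (py - xyz[k, 2])^2 +
                        (pz - xyz[k, 3])^2 > rexp[k]^2)
    }
    acc <- acc + wt[t] * sum(free)
  }
  rexp[i]^2 * acc
}

# Random rigid motion applied to an x/y/z data frame.
apply_rigid <- function(df, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # random rotation via QR of a Gaussian matrix
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t <- rnorm(3, sd = 5)
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% Q
  df$x <- xyz[, 1] + t[1]
  df$y <- xyz[, 2] + t[2]
  df$z <- xyz[, 3] + t[3]
  df
}

# Small random grid as an fes_grid for path tests.
random_fes <- function(n1, n2, per1 = FALSE, per2 = FALSE, seed = 1) {
  set.seed(seed)
  axes <- list(grid_axis("phi", 0, 2 * pi, n1, periodic = per1),
               grid_axis("theta", 0, pi, n2, periodic = per2))
  as_fes_grid(matrix(stats::runif(n1 * n2, 0, 10), n1, n2), axes)
}
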