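# Cremer-Pople puckering analysis of six-membered rings.

#' Validate a six-atom ring geometry
#'
#' A ring geometry is a data frame with one row per ring atom in ring-walk
#' order (O5, C1, ..., C5 for a pyranose) and columns `x`, `y`, `z` in
#' Angstrom.  An optional `label` column carries atom names.
#'
#' @param ring data frame with columns `x`, `y`, `z` (6 rows).
#' @param bond_range allowed consecutive-atom distances in Angstrom.
#' @return the validated geometry, invisibly.
#' @keywords internal
validate_ring <- function(ring, bond_range = c(1.2, 1.8)) {
  check_columns(ring, c("x", "y", "z"), "ring geometry")
  if (nrow(ring) != 6) {
    abort(sprintf("a ring geometry needs exactly 6 atoms, got %d", nrow(ring)))
  }
  xyz <- as.matrix(ring[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("ring coordinates must be finite")
  d <- as.matrix(stats::dist(xyz))
  if (any(d[upper.tri(d)] < 1e-6)) abort("ring contains coincident atoms")
  nxt <- c(2:6, 1)
  bonds <- sqrt(rowSums((xyz[nxt, , drop = FALSE] - xyz)^2))
  if (any(bonds < bond_range[1] | bonds > bond_range[2])) {
    abort(sprintf(
      "consecutive ring atoms must be %.1f-%.1f Angstrom apart (found %.2f-%.2f)",
      bond_range[1], bond_range[2], min(bonds), max(bonds)))
  }
  invisible(ring)
}

# Core forward map on a 6x3 coordinate matrix; angles in radians.
.cp_forward <- function(xyz) {
  ctr <- colMeans(xyz)
  R <- sweep(xyz, 2, ctr)
  j <- 0:5
  a <- 2 * pi * j / 6
  Rp <- colSums(R * sin(a))
  Rpp <- colSums(R * cos(a))
  n <- c(
    Rp[2] * Rpp[3] - Rp[3] * Rpp[2],
    Rp[3] * Rpp[1] - Rp[1] * Rpp[3],
    Rp[1] * Rpp[2] - Rp[2] * Rpp[1]
  )
  n <- n / sqrt(sum(n^2))
  z <- as.vector(R %*% n)
  q2c <- sqrt(1 / 3) * sum(z * cos(2 * a))
  q2s <- -sqrt(1 / 3) * sum(z * sin(2 * a))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  list(Q = sqrt(q2^2 + q3^2),
       theta = atan2(q2, q3),
       phi = wrap_period(atan2(q2s, q2c)))
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the total puckering amplitude Q (Angstrom) and the spherical
#' angles theta and phi from the atom displacements perpendicular to the
#' ring mean plane.  With the O5-first ring walk, theta = 0 is the 4C1
#' chair of an alpha-D-pyranose and theta = 180 the inverted 1C4 chair;
#' phi runs 0-360 around the equator of boats and skew-boats.
#'
#' For a near-planar ring (Q below `q_tol`) the angles are undefined and
#' the result is flagged degenerate rather than raising an error.
#'
#' @param ring ring geometry data frame (see [validate_ring()]); if a
#'   `frame` column is present, one result row is returned per frame.
#' @param degrees report theta/phi in degrees (default) or radians.
#' @param q_tol amplitude below which the ring counts as planar (Angstrom).
#' @return tibble with columns `Q`, `theta`, `phi`, `degenerate` (and
#'   `frame` when the input had one).
#' @examples
#' ring <- make_ring(Q = 0.55, theta = 90, phi = 210)
#' cremer_pople(ring)
#' @export
cremer_pople <- function(ring, degrees = TRUE, q_tol = 1e-4) {
  if ("frame" %in% names(ring)) {
    out <- ring |>
      dplyr::group_by(.data$frame) |>
      dplyr::group_modify(~ cremer_pople(dplyr::select(.x, -dplyr::any_of("frame")),
                                         degrees = degrees, q_tol = q_tol)) |>
      dplyr::ungroup()
    return(out)
  }
  validate_ring(ring)
  cp <- .cp_forward(as.matrix(ring[, c("x", "y", "z")]))
  degenerate <- cp$Q < q_tol
  theta <- if (degenerate) NA_real_ else cp$theta
  phi <- if (degenerate) NA_real_ else cp$phi
  if (degrees && !degenerate) {
    theta <- rad2deg(theta)
    phi <- rad2deg(phi)
  }
  tibble(Q = cp$Q, theta = theta, phi = phi, degenerate = degenerate)
}

#' Build a ring geometry with prescribed puckering coordinates
#'
#' Inverse of [cremer_pople()]: places the six atoms on a reference hexagon
#' and adds the out-of-plane displacements that realize the requested
#' (Q, theta, phi).  The hexagon radius is shrunk so the mean squared bond
#' length matches `bond_length`; the forward map recovers the target
#' coordinates to better than 1e-6.
#'
#' @param Q puckering amplitude, Angstrom (>= 0).
#' @param theta,phi target angles (degrees by default).
#' @param bond_length target mean ring bond length, Angstrom.
#' @param degrees interpret theta/phi as degrees.
#' @return ring geometry tibble with columns `label`, `x`, `y`, `z`.
#' @examples
#' invert_cremer_pople(0.6, theta = 0, phi = 0)
#' @export
invert_cremer_pople <- function(Q, theta, phi, bond_length = 1.54,
                                degrees = TRUE) {
  if (Q < 0) abort("Q must be non-negative")
  if (degrees) {
    theta <- deg2rad(theta)
    phi <- deg2rad(phi)
  }
  j <- 0:5
  a <- 2 * pi * j / 6
  q2 <- Q * sin(theta)
  q3 <- Q * cos(theta)
  z <- sqrt(1 / 3) * q2 * cos(phi + 2 * a) + sqrt(1 / 6) * q3 * (-1)^j
  dz2 <- (z[c(2:6, 1)] - z)^2
  side2 <- bond_length^2 - mean(dz2)
  if (side2 <= 0.5) {
    abort(sprintf("amplitude Q = %.3f is infeasible for bond length %.2f",
                  Q, bond_length))
  }
  rho <- sqrt(side2)  # regular hexagon: side equals circumradius
  # Clockwise walk (viewed from +z) so the mean-plane normal of the forward
  # map points along +z and the prescribed displacements are recovered.
  tibble(
    label = c("O5", "C1", "C2", "C3", "C4", "C5"),
    x = rho * cos(a),
    y = -rho * sin(a),
    z = z
  )
}

#' Classify puckering coordinates onto the canonical conformer set
#'
#' Assigns each (theta, phi) point the canonical conformer whose reference
#' position minimizes great-circle distance on the puckering sphere.  Ties
#' are broken deterministically by the fixed order of [cp_conformers()].
#'
#' @param pucker data frame with columns `theta` and `phi` (degrees), e.g.
#'   the output of [cremer_pople()]; rows flagged `degenerate` raise an
#'   error.
#' @param degrees interpret input angles as degrees.
#' @return the input tibble with `label`, `conformer_type` and
#'   `ref_distance` (great-circle distance to the reference, degrees)
#'   appended.
#' @examples
#' classify_conformer(tibble::tibble(theta = 2, phi = 100))
#' @export
classify_conformer <- function(pucker, degrees = TRUE) {
  check_columns(pucker, c("theta", "phi"), "puckering table")
  degen <- "degenerate" %in% names(pucker) && any(pucker$degenerate)
  if (any(!is.finite(pucker$theta) | !is.finite(pucker$phi)) || degen) {
    abort("cannot classify degenerate (planar) puckering coordinates")
  }
  tab <- .conformer_table()
  th <- if (degrees) deg2rad(pucker$theta) else pucker$theta
  ph <- if (degrees) deg2rad(pucker$phi) else pucker$phi
  th_ref <- deg2rad(tab$theta_ref)
  ph_ref <- deg2rad(tab$phi_ref)
  idx <- integer(length(th))
  dmin <- numeric(length(th))
  for (i in seq_along(th)) {
    d <- great_circle(th[i], ph[i], th_ref, ph_ref)
    idx[i] <- which.min(d)  # which.min takes the first: fixed-order tie-break
    dmin[i] <- d[idx[i]]
  }
  dplyr::bind_cols(
    as_tibble(pucker),
    tibble(label = tab$label[idx],
           conformer_type = tab$type[idx],
           ref_distance = rad2deg(dmin))
  )
}

#' Reactive/nonreactive partition of the puckering sphere
#'
#' The partition separates the northern region around the 4C1 chair
#' (reactive: conformations poised to reach the transition-state space)
#' from the southern region toward 1C4 (nonreactive).  The boundary is a
#' polyline theta_b(phi) closing periodically in phi; the default is the
#' equator (theta_b = 90 for all phi), owned by the nonreactive side,
#' which places E5 in the reactive and 1S3 in the nonreactive region.
#'
#' @param phi,theta_b boundary polyline vertices, degrees; `theta_b` is
#'   recycled to the length of `phi`.
#' @param inclusive_side which region owns points exactly on the boundary,
#'   `"nonreactive"` (default) or `"reactive"`.
#' @return an object of class `partition_spec`.
#' @examples
#' partition_spec()                     # equator boundary
#' partition_spec(phi = c(0, 180), theta_b = c(85, 95))
#' @export
partition_spec <- function(phi = 0, theta_b = 90,
                           inclusive_side = c("nonreactive", "reactive")) {
  inclusive_side <- match.arg(inclusive_side)
  theta_b <- rep_len(theta_b, length(phi))
  if (any(theta_b <= 0 | theta_b >= 180)) {
    abort("boundary theta_b must lie strictly inside (0, 180) degrees")
  }
  ord <- order(phi %% 360)
  structure(
    list(phi = (phi %% 360)[ord], theta_b = theta_b[ord],
         inclusive_side = inclusive_side),
    class = "partition_spec"
  )
}

#' @export
print.partition_spec <- function(x, ...) {
  cat("Puckering-sphere partition\n")
  if (length(x$phi) == 1) {
    cat(sprintf("  boundary: constant theta = %g deg\n", x$theta_b))
  } else {
    cat(sprintf("  boundary: polyline with %d vertices (theta %g-%g deg)\n",
                length(x$phi), min(x$theta_b), max(x$theta_b)))
  }
  cat(sprintf("  boundary owned by the %s side\n", x$inclusive_side))
  invisible(x)
}

# Boundary theta_b(phi) by periodic linear interpolation, degrees in/out.
boundary_theta <- function(spec, phi) {
  phi <- phi %% 360
  if (length(spec$phi) == 1) return(rep(spec$theta_b, length(phi)))
  xs <- c(spec$phi, spec$phi[1] + 360)
  ys <- c(spec$theta_b, spec$theta_b[1])
  # shift query points below the first vertex up by one period
  phi_q <- ifelse(phi < xs[1], phi + 360, phi)
  stats::approx(xs, ys, xout = phi_q, rule = 2)$y
}

#' Reactive-conformation membership on the puckering sphere
#'
#' A puckering point is reactive when it lies strictly north of the
#' partition boundary (theta < theta_b(phi)); points exactly on the
#' boundary belong to the side named by the partition's `inclusive_side`.
#'
#' @param pucker data frame with `theta`, `phi` in degrees (rows must not
#'   be degenerate).
#' @param spec a [partition_spec()].
#' @return logical vector, `TRUE` for reactive rows.
#' @examples
#' is_reactive(tibble::tibble(theta = 55, phi = 300))  # E5-like: reactive
#' @export
is_reactive <- function(pucker, spec = partition_spec()) {
  check_columns(pucker, c("theta", "phi"), "puckering table")
  degen <- "degenerate" %in% names(pucker) && any(pucker$degenerate)
  if (any(!is.finite(pucker$theta)) || degen) {
    abort("cannot assign degenerate (planar) puckering coordinates to a region")
  }
  tb <- boundary_theta(spec, pucker$phi)
  if (spec$inclusive_side == "reactive") {
    pucker$theta <= tb
  } else {
    pucker$theta < tb
  }
}

#' Extract a ring geometry from a PDB structure
#'
#' Pulls the six ring atoms of one residue from a PDB file (or a parsed
#' bio3d `pdb` object), in the given ring-walk order.
#'
#' @param pdb path to a PDB file or a `bio3d::read.pdb()` object.
#' @param resno residue number holding the ring.
#' @param atoms ring-walk atom names, default `c("O5","C1","C2","C3","C4","C5")`.
#' @param chain optional chain identifier.
#' @return ring geometry tibble (`label`, `x`, `y`, `z`).
#' @export
ring_from_pdb <- function(pdb, resno,
                          atoms = c("O5", "C1", "C2", "C3", "C4", "C5"),
                          chain = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  sel <- at$resno == resno & at$elety %in% atoms
  if (!is.null(chain)) sel <- sel & at$chain == chain
  at <- at[sel, , drop = FALSE]
  idx <- match(atoms, at$elety)
  if (anyNA(idx)) {
    abort(sprintf("residue %s does not resolve ring atoms: missing %s",
                  resno, paste(atoms[is.na(idx)], collapse = ", ")))
  }
  at <- at[idx, , drop = FALSE]
  tibble(label = atoms, x = at$x, y = at$y, z = at$z)
}
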