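# Canonical ring-conformer reference table.
#
# The 38 canonical conformers of a six-membered ring (2 chairs, 6 boats,
# 6 skew-boats, 12 envelopes, 12 half-chairs) are placed on the puckering
# sphere by projecting their idealized out-of-plane displacement patterns
# through the same Cremer-Pople sums used by the forward map, so the table
# is self-consistent with `cremer_pople()` by construction.  Ring walk is
# O5, C1, C2, C3, C4, C5 (O5 first), the dominant glycoscience convention,
# under which the 4C1 chair sits at the north pole (theta = 0).

# Atom index helper: O5 = 1, C1 = 2, ..., C5 = 6.
.ring_atom_index <- c(O5 = 1L, C1 = 2L, C2 = 3L, C3 = 4L, C4 = 5L, C5 = 6L)

# Project a raw z-displacement pattern (length 6) onto (theta, phi) via the
# Cremer-Pople amplitude sums.  Constant and single-wave components of z do
# not contribute (they are orthogonal to the m = 2, 3 sums), so idealized
# sign patterns can be used directly.
.cp_project_z <- function(z) {
  j <- 0:5
  a <- 2 * pi * j / 6
  q2c <- sqrt(1 / 3) * sum(z * cos(2 * a))
  q2s <- -sqrt(1 / 3) * sum(z * sin(2 * a))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  list(
    theta = atan2(q2, q3),
    phi = wrap_period(atan2(q2s, q2c))
  )
}

.unit_at <- function(up = character(), down = character()) {
  z <- numeric(6)
  z[.ring_atom_index[up]] <- 1
  z[.ring_atom_index[down]] <- -1
  z
}

.conformer_patterns <- function() {
  atoms <- names(.ring_atom_index)
  pat <- list()

  # Chairs: alternating signs; 4C1 has O5, C2, C4 above the mean plane.
  pat[["4C1"]] <- list(type = "chair", z = rep(c(1, -1), 3))
  pat[["1C4"]] <- list(type = "chair", z = rep(c(-1, 1), 3))

  # Boats: a para pair displaced to the same side.
  boat_pairs <- list(c("O5", "C3"), c("C1", "C4"), c("C2", "C5"))
  boat_tags <- c("O3", "14", "25")
  for (k in seq_along(boat_pairs)) {
    pat[[paste0(boat_tags[k], "B")]] <-
      list(type = "boat", z = .unit_at(up = boat_pairs[[k]]))
    pat[[paste0("B", boat_tags[k])]] <-
      list(type = "boat", z = .unit_at(down = boat_pairs[[k]]))
  }

  # Skew-boats (twist-boats): a meta pair displaced to opposite sides.
  skews <- list(
    "3S1" = c("C3", "C1"), "5S1" = c("C5", "C1"), "2SO" = c("C2", "O5"),
    "1S3" = c("C1", "C3"), "1S5" = c("C1", "C5"), "OS2" = c("O5", "C2")
  )
  for (nm in names(skews)) {
    pat[[nm]] <- list(type = "skew-boat",
                      z = .unit_at(up = skews[[nm]][1], down = skews[[nm]][2]))
  }

  # Envelopes: one atom out of plane (superscript above, subscript below).
  env_tag <- sub("^[OC]", "", atoms)  # O5 -> "O" label uses O, carbons use number
  env_tag <- c("O", "1", "2", "3", "4", "5")
  for (k in seq_along(atoms)) {
    pat[[paste0(env_tag[k], "E")]] <- list(type = "envelope",
                                           z = .unit_at(up = atoms[k]))
    pat[[paste0("E", env_tag[k])]] <- list(type = "envelope",
                                           z = .unit_at(down = atoms[k]))
  }

  # Half-chairs: adjacent pair on opposite sides.
  nxt <- c(2:6, 1)
  for (k in seq_along(atoms)) {
    up <- atoms[k]; down <- atoms[nxt[k]]
    pat[[paste0(env_tag[k], "H", env_tag[nxt[k]])]] <-
      list(type = "half-chair", z = .unit_at(up = up, down = down))
    pat[[paste0(env_tag[nxt[k]], "H", env_tag[k])]] <-
      list(type = "half-chair", z = .unit_at(up = atoms[nxt[k]], down = atoms[k]))
  }

  pat
}

#' Canonical conformer reference table
#'
#' Reference coordinates of the 38 canonical six-ring conformers on the
#' Cremer-Pople sphere: 2 chairs at the poles, 6 boats and 6 skew-boats on
#' the equator at 30-degree phi spacing, and 12 envelopes plus 12
#' half-chairs on the northern/southern tropics.  Labels use a plain-ASCII
#' rendering of the IUPAC names: `4C1` for the chair with C4 above and C1
#' below the ring plane, `1S3`, `B25`, `E5`, `4H5`, `OS2`, and so on, with
#' `O` standing for the ring oxygen O5.
#'
#' @return A tibble with columns `label`, `type` (chair, boat, skew-boat,
#'   envelope, half-chair), `theta_ref` and `phi_ref` (degrees).
#' @examples
#' cp_conformers()
#' @export
cp_conformers <- function() {
  pat <- .conformer_patterns()
  proj <- lapply(pat, function(p) .cp_project_z(p$z))
  tibble(
    label = names(pat),
    type = unname(vapply(pat, `[[`, character(1), "type")),
    theta_ref = rad2deg(unname(vapply(proj, `[[`, numeric(1), "theta"))),
    phi_ref = rad2deg(unname(vapply(proj, `[[`, numeric(1), "phi")))
  )
}

# Cached copy (the table is deterministic).
.conformer_cache <- new.env(parent = emptyenv())

.conformer_table <- function() {
  if (is.null(.conformer_cache$tab)) .conformer_cache$tab <- cp_conformers()
  .conformer_cache$tab
}
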