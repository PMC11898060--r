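# Shrake-Rupley solvent-accessible surface area and the
# substrate-positioning index (SPI).

#' Deterministic quasi-uniform sphere points
#'
#' Fibonacci-spiral point set on the unit sphere.  No randomness: the same
#' `n` always yields the same points, so areas are bit-stable across runs.
#'
#' @param n number of points.
#' @return an `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 1) abort("need at least one sphere point")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# van der Waals radii (Angstrom) keyed by element symbol.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                ZN = 1.39, MG = 1.73, CA = 1.97, FE = 1.56, "NA" = 2.27,
                K = 2.75)

#' Look up van der Waals radii by element
#'
#' @param element character vector of element symbols.
#' @param default radius for unknown elements, Angstrom.
#' @return numeric vector of radii.
#' @export
vdw_radius <- function(element, default = 1.70) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- default
  unname(r)
}

.atom_radii <- function(atoms) {
  if ("radius" %in% names(atoms)) return(atoms$radius)
  if ("element" %in% names(atoms)) return(vdw_radius(atoms$element))
  abort("atoms need a 'radius' or 'element' column")
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, test points on its solvent-expanded sphere (radius
#' `r + probe`) are checked against the expanded spheres of all other
#' atoms; the accessible fraction times `4*pi*(r+probe)^2` is the atom's
#' area.  The point set is a deterministic Fibonacci spiral.
#'
#' With `hydrogens = "united"` hydrogen atoms are dropped and heavy-atom
#' radii inflated by `united_pad` to absorb them.
#'
#' @param atoms tibble with `x`, `y`, `z` (Angstrom) and either a `radius`
#'   or an `element` column.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points test points per sphere.
#' @param hydrogens `"explicit"` (default: use atoms as given) or
#'   `"united"`.
#' @param united_pad radius inflation for the united-atom option, Angstrom.
#' @return the input tibble with an `area` column (Angstrom^2) appended.
#' @examples
#' a <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.5)
#' shrake_rupley(a)$area          # ~ 4*pi*(2.9)^2
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960,
                          hydrogens = c("explicit", "united"),
                          united_pad = 0.1) {
  hydrogens <- match.arg(hydrogens)
  check_columns(atoms, c("x", "y", "z"), "atom table")
  if (probe < 0) abort("probe radius must be non-negative")
  atoms <- as_tibble(atoms)
  atoms$radius <- .atom_radii(atoms)
  if (any(atoms$radius <= 0)) abort("atom radii must be positive")
  if (hydrogens == "united" && "element" %in% names(atoms)) {
    keep <- toupper(atoms$element) != "H"
    atoms <- atoms[keep, , drop = FALSE]
    atoms$radius <- atoms$radius + united_pad
  }

  n <- nrow(atoms)
  pts <- sphere_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rexp <- atoms$radius + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    # candidate occluders
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nbr <- which(d2 < (rexp + rexp[i])^2 & seq_len(n) != i)
    if (length(nbr) == 0) {
      area[i] <- 4 * pi * rexp[i]^2
      next
    }
    p <- sweep(pts * rexp[i], 2, xyz[i, ], `+`)   # n_points x 3
    free <- rep(TRUE, n_points)
    for (k in nbr) {
      if (!any(free)) break
      dd <- (p[free, 1] - xyz[k, 1])^2 + (p[free, 2] - xyz[k, 2])^2 +
        (p[free, 3] - xyz[k, 3])^2
      free[free] <- dd > rexp[k]^2
    }
    area[i] <- 4 * pi * rexp[i]^2 * sum(free) / n_points
  }
  atoms$area <- area
  atoms
}

#' Substrate-positioning index (SPI)
#'
#' Per-atom areas are computed in the context of the full structure (every
#' atom occludes), then summed over the `substrate` and `pocket` groups:
#' SPI = SASAsub / SASApkt.  With a `frame` column, per-frame values plus
#' their mean and standard deviation are returned.
#'
#' @param atoms tibble with coordinates, radii (or elements) and a `group`
#'   column containing at least `"substrate"` and `"pocket"` (other values
#'   occlude but are not summed).
#' @inheritParams shrake_rupley
#' @return tibble with `sasa_sub`, `sasa_pkt`, `spi` (and `frame` columns
#'   plus a summary attribute when multiple frames are given).  A zero
#'   pocket area yields `spi = NA` with a warning (degenerate ratio).
#' @export
spi <- function(atoms, probe = 1.4, n_points = 960,
                hydrogens = c("explicit", "united")) {
  hydrogens <- match.arg(hydrogens)
  check_columns(atoms, "group", "atom table")
  if (!any(atoms$group == "substrate") || !any(atoms$group == "pocket")) {
    abort("both 'substrate' and 'pocket' groups must be non-empty")
  }
  one <- function(fr) {
    res <- shrake_rupley(fr, probe = probe, n_points = n_points,
                         hydrogens = hydrogens)
    sub <- sum(res$area[res$group == "substrate"])
    pkt <- sum(res$area[res$group == "pocket"])
    if (pkt == 0) {
      warn("pocket SASA is zero: SPI undefined")
      ratio <- NA_real_
    } else {
      ratio <- sub / pkt
    }
    tibble(sasa_sub = sub, sasa_pkt = pkt, spi = ratio)
  }
  if ("frame" %in% names(atoms)) {
    out <- atoms |>
      dplyr::group_by(.data$frame) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
    attr(out, "summary") <- tibble(
      spi_mean = mean(out$spi, na.rm = TRUE),
      spi_sd = stats::sd(out$spi, na.rm = TRUE)
    )
    out
  } else {
    one(atoms)
  }
}

#' Atom set from a PDB structure with substrate/pocket grouping
#'
#' @param pdb path or `bio3d::read.pdb()` object.
#' @param substrate_res residue numbers forming the substrate group.
#' @param pocket_res residue numbers forming the active-site pocket group.
#' @return atom tibble (`element`, `x`, `y`, `z`, `group`) ready for [spi()].
#' @export
atoms_from_pdb <- function(pdb, substrate_res, pocket_res) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  grp <- rep("other", nrow(at))
  grp[at$resno %in% substrate_res] <- "substrate"
  grp[at$resno %in% pocket_res] <- "pocket"
  tibble(element = ifelse(is.na(at$elesy) | at$elesy == "",
                          substr(trimws(at$elety), 1, 1), at$elesy),
         x = at$x, y = at$y, z = at$z, group = grp)
}
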