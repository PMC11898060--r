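# Reaction collective variables and catalytic observables.
#
# The two CVs describe the glycosylation step of a retaining glycosidase:
# CV1 follows the proton transfer from the general acid/base (D319) to the
# glycosidic oxygen, CV2 the glycosidic bond cleavage plus nucleophilic
# attack by D196 on the anomeric carbon C1'.

#' Catalytic atom selection
#'
#' Names the atoms needed for the reaction CVs within a structure:
#' the acid/base carboxylate oxygen pair and its proton (D319 in the
#' wild-type enzyme), the glycosidic oxygen, the nucleophile carboxylate
#' pair and attacking oxygen (D196), the anomeric carbon and the ring
#' oxygen.  Each entry is `c(residue_number, atom_name)`.  Atom names
#' follow common force-field conventions and are fully overridable because
#' deposited naming for the substrate and a protonated aspartate may vary.
#'
#' @param acid_res,nuc_res,substrate_res residue numbers of the acid/base,
#'   nucleophile, and substrate.
#' @param acid_atoms,nuc_atoms the two carboxylate oxygen names of each.
#' @param proton name of the transferred proton on the acid residue.
#' @param o_g,c1p,o_ring substrate atom names: glycosidic oxygen, anomeric
#'   carbon, ring oxygen.
#' @param o_a name of the acid oxygen bearing the proton; `o_n` the
#'   attacking nucleophile oxygen.
#' @return a `catalytic_selection` list.
#' @export
catalytic_selection <- function(acid_res = 319, acid_atoms = c("OD1", "OD2"),
                                proton = "HD2",
                                nuc_res = 196, nuc_atoms = c("OD1", "OD2"),
                                o_n = "OD1",
                                substrate_res = 1,
                                o_g = "O6", c1p = "C1", o_ring = "O5",
                                o_a = "OD2") {
  if (acid_atoms[1] == acid_atoms[2] || nuc_atoms[1] == nuc_atoms[2]) {
    abort("carboxylate oxygen pairs must name two distinct atoms")
  }
  structure(
    list(
      acid_o1 = c(acid_res, acid_atoms[1]),
      acid_o2 = c(acid_res, acid_atoms[2]),
      o_a = c(acid_res, o_a),
      h_a = c(acid_res, proton),
      nuc_o1 = c(nuc_res, nuc_atoms[1]),
      nuc_o2 = c(nuc_res, nuc_atoms[2]),
      o_n = c(nuc_res, o_n),
      o_g = c(substrate_res, o_g),
      c1p = c(substrate_res, c1p),
      o_ring = c(substrate_res, o_ring)
    ),
    class = "catalytic_selection"
  )
}

#' Resolve a catalytic frame from a PDB structure
#'
#' @param pdb path to a PDB file or a `bio3d::read.pdb()` object.
#' @param selection a [catalytic_selection()].
#' @return a catalytic frame: tibble with columns `role`, `x`, `y`, `z`
#'   (Angstrom), one row per selection entry.
#' @export
catalytic_frame_from_pdb <- function(pdb, selection = catalytic_selection()) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  rows <- purrr::imap(unclass(selection), function(sel, role) {
    hit <- which(at$resno == as.integer(sel[1]) & at$elety == sel[2])
    if (length(hit) != 1) {
      abort(sprintf("selection '%s' (resno %s, atom %s) resolves %d atoms",
                    role, sel[1], sel[2], length(hit)))
    }
    tibble(role = role, x = at$x[hit], y = at$y[hit], z = at$z[hit])
  })
  bind_rows(rows)
}

# Pull one atom's coordinates (length-3 vector) out of a frame.
.frame_xyz <- function(frame, role) {
  r <- which(frame$role == role)
  if (length(r) != 1) abort(sprintf("frame does not resolve atom '%s'", role))
  v <- c(frame$x[r], frame$y[r], frame$z[r])
  if (!all(is.finite(v))) abort(sprintf("atom '%s' has non-finite coordinates", role))
  v
}

.dist <- function(a, b) sqrt(sum((a - b)^2))

#' Proton-transfer collective variable CV1
#'
#' `d1 - d2`, where d1 is the distance from the centre of mass of the
#' acid/base carboxylate oxygen pair (equal masses, so their midpoint) to
#' the transferred proton H_a, and d2 the distance from H_a to the
#' glycosidic oxygen O_g.  Negative before transfer, positive after.
#'
#' @param frame catalytic frame tibble (`role`, `x`, `y`, `z`).
#' @return CV1 in Angstrom.
#' @export
cv1 <- function(frame) {
  mid <- (.frame_xyz(frame, "acid_o1") + .frame_xyz(frame, "acid_o2")) / 2
  ha <- .frame_xyz(frame, "h_a")
  .dist(mid, ha) - .dist(ha, .frame_xyz(frame, "o_g"))
}

#' Bond-cleavage / nucleophilic-attack collective variable CV2
#'
#' `d3 - d4`, where d3 is the glycosidic O_g to anomeric carbon C1'
#' distance and d4 the distance from C1' to the midpoint of the
#' nucleophile carboxylate oxygen pair.
#'
#' @inheritParams cv1
#' @return CV2 in Angstrom.
#' @export
cv2 <- function(frame) {
  c1 <- .frame_xyz(frame, "c1p")
  mid <- (.frame_xyz(frame, "nuc_o1") + .frame_xyz(frame, "nuc_o2")) / 2
  .dist(.frame_xyz(frame, "o_g"), c1) - .dist(c1, mid)
}

#' Catalytic distance observables
#'
#' The four distances conventionally tracked along the glycosylation step:
#' C1'-O_g (glycosidic bond), O_n-C1' (nucleophilic attack), O_a-H_a
#' (acid O-H) and H_a-O_g (proton to leaving-group oxygen).
#'
#' @inheritParams cv1
#' @return one-row tibble, distances in Angstrom.
#' @export
catalytic_distances <- function(frame) {
  c1 <- .frame_xyz(frame, "c1p")
  og <- .frame_xyz(frame, "o_g")
  ha <- .frame_xyz(frame, "h_a")
  tibble(
    d_c1p_og = .dist(c1, og),
    d_on_c1p = .dist(.frame_xyz(frame, "o_n"), c1),
    d_oa_ha = .dist(.frame_xyz(frame, "o_a"), ha),
    d_ha_og = .dist(ha, og)
  )
}

#' Nucleophilic attack angle
#'
#' Interior angle O_n - C1' - O_ring at the anomeric carbon, degrees.
#'
#' @inheritParams cv1
#' @return angle in degrees, in `[0, 180]`.
#' @export
attack_angle <- function(frame) {
  c1 <- .frame_xyz(frame, "c1p")
  v1 <- .frame_xyz(frame, "o_n") - c1
  v2 <- .frame_xyz(frame, "o_ring") - c1
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) abort("attack angle undefined: zero-length vector")
  rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))))
}

#' All reaction-geometry observables per frame
#'
#' Convenience wrapper computing CV1, CV2, the four catalytic distances
#' and the attack angle; with a `frame` column, one row per frame.
#'
#' @param frames catalytic frame tibble, optionally with a `frame` column.
#' @return tibble with `cv1`, `cv2`, the distance columns and `attack_angle`.
#' @export
reaction_cvs <- function(frames) {
  one <- function(fr) {
    dplyr::bind_cols(
      tibble(cv1 = cv1(fr), cv2 = cv2(fr)),
      catalytic_distances(fr),
      tibble(attack_angle = attack_angle(fr))
    )
  }
  if ("frame" %in% names(frames)) {
    frames |>
      dplyr::group_by(.data$frame) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(frames)
  }
}
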