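# Backbone representation, internal/Cartesian conversion, superposition and
# ring-closure diagnostics for head-to-tail cyclic peptides.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Ideal backbone covalent geometry
#'
#' Standard polymer bond lengths and angles used when realising torsion
#' angles as Cartesian coordinates and when measuring ring-closure
#' deviations. All values are configurable; the defaults are the usual
#' peptide-backbone values (lengths in Angstrom, angles in degrees).
#'
#' @param n_ca,ca_c,c_n,c_o bond lengths in Angstrom.
#' @param n_ca_c,ca_c_n,c_n_ca,ca_c_o bond angles in degrees.
#' @return an object of class `ideal_geometry` (a named list).
#' @export
ideal_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                           c_o = 1.231, n_ca_c = 111.2, ca_c_n = 116.2,
                           c_n_ca = 121.7, ca_c_o = 120.1) {
  vals <- list(
    n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
    n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca, ca_c_o = ca_c_o
  )
  if (any(unlist(vals) <= 0)) abort_invalid("ideal geometry values must be strictly positive")
  structure(vals, class = "ideal_geometry")
}

#' Construct a backbone object
#'
#' A backbone holds the N, CA, C and O coordinates of every residue of a
#' single-chain peptide, plus a flag marking head-to-tail cyclisation
#' (an amide bond between C of the last residue and N of residue 1).
#'
#' @param N,CA,C,O numeric L x 3 matrices of atom coordinates in Angstrom.
#' @param cyclic logical; head-to-tail macrocycle?
#' @param id free-text identifier.
#' @return an object of class `backbone`.
#' @export
backbone <- function(N, CA, C, O, cyclic = TRUE, id = "backbone") {
  mats <- list(N = N, CA = CA, C = C, O = O)
  L <- nrow(N)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != L) {
      abort_invalid(sprintf("atom matrix %s must be an L x 3 matrix", nm))
    }
    if (!all(is.finite(m))) abort_invalid(sprintf("non-finite coordinates in %s", nm))
  }
  if (L < 3) abort_invalid("a backbone needs at least 3 residues")
  structure(
    list(N = N, CA = CA, C = C, O = O, cyclic = isTRUE(cyclic), id = as.character(id)),
    class = "backbone"
  )
}

#' @export
length.backbone <- function(x) nrow(x$N)

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf(
    "<backbone '%s': %d residues, %s>\n", x$id, length(x),
    if (x$cyclic) "head-to-tail cyclic" else "linear"
  ))
  invisible(x)
}

#' Stack selected backbone atoms into one point matrix
#'
#' Residue-major ordering: all selected atoms of residue 1, then residue 2,
#' and so on.
#'
#' @param bb a [backbone()].
#' @param atoms character subset of `c("N", "CA", "C", "O")`.
#' @return an (L * length(atoms)) x 3 matrix.
#' @export
backbone_atom_matrix <- function(bb, atoms = BACKBONE_ATOMS) {
  atoms <- match.arg(atoms, BACKBONE_ATOMS, several.ok = TRUE)
  L <- length(bb)
  out <- matrix(0, L * length(atoms), 3)
  for (k in seq_along(atoms)) {
    out[seq(k, by = length(atoms), length.out = L), ] <- bb[[atoms[k]]]
  }
  out
}

#' Construct a torsion set
#'
#' Per-residue backbone dihedrals (phi, psi, omega) in degrees, wrapped to
#' (-180, 180]. In cyclic mode every angle is defined (terminal dihedrals
#' wrap around the ring); in linear mode phi of residue 1 and psi/omega of
#' the last residue are `NA` (undefined).
#'
#' @param phi,psi,omega numeric vectors of equal length (degrees).
#' @param cyclic logical.
#' @return an object of class `torsion_set`.
#' @export
torsion_set <- function(phi, psi, omega, cyclic = TRUE) {
  L <- length(phi)
  if (length(psi) != L || length(omega) != L) {
    abort_invalid("phi, psi and omega must have equal length")
  }
  structure(
    list(
      phi = wrap_angle(phi), psi = wrap_angle(psi), omega = wrap_angle(omega),
      cyclic = isTRUE(cyclic)
    ),
    class = "torsion_set"
  )
}

#' @export
length.torsion_set <- function(x) length(x$phi)

# NeRF atom placement: returns point d with |c-d| = bond, angle(b,c,d) =
# `angle` and dihedral(a,b,c,d) = `torsion` (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(tor),
    -bond * sin(ang) * sin(tor)
  )
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Build Cartesian coordinates from backbone torsions
#'
#' Sequential internal-coordinate (NeRF) chain building with ideal covalent
#' geometry. Residue 1 is placed in a canonical frame: N at the origin, CA
#' on the +x axis, C in the xy-plane. Carbonyl oxygens are placed in the
#' CA-C-N(next) plane, anti to the next nitrogen. The returned backbone is
#' not guaranteed to be ring-closed; closure is [close_ring()]'s job.
#'
#' @param torsions a [torsion_set()]; all angles must be defined
#'   (cyclic wrap conventions).
#' @param geom an [ideal_geometry()].
#' @param id identifier for the new backbone.
#' @return a [backbone()] with the `cyclic` flag copied from `torsions`.
#' @export
torsions_to_backbone <- function(torsions, geom = ideal_geometry(),
                                 id = "from_torsions") {
  L <- length(torsions)
  if (L < 3) abort_invalid("need at least 3 residues")
  if (anyNA(c(torsions$phi, torsions$psi, torsions$omega))) {
    abort_invalid("all torsions must be defined to build coordinates")
  }
  N <- CA <- C <- O <- matrix(0, L, 3)
  th <- deg2rad(geom$n_ca_c)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(geom$n_ca, 0, 0)
  C[1, ] <- CA[1, ] + geom$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], geom$c_n, geom$ca_c_n, torsions$psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], geom$n_ca, geom$c_n_ca, torsions$omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], geom$ca_c, geom$n_ca_c, torsions$phi[i + 1])
    O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], geom$c_o, geom$ca_c_o, 180)
  }
  # last O uses a virtual next nitrogen continued from psi(L)
  vN <- place_atom(N[L, ], CA[L, ], C[L, ], geom$c_n, geom$ca_c_n, torsions$psi[L])
  O[L, ] <- place_atom(vN, CA[L, ], C[L, ], geom$c_o, geom$ca_c_o, 180)
  backbone(N, CA, C, O, cyclic = torsions$cyclic, id = id)
}

#' Measure backbone torsions from coordinates
#'
#' Standard dihedral definitions: phi(i) = C(i-1)-N(i)-CA(i)-C(i),
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1), omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1).
#' The backbone's `cyclic` flag controls whether terminal angles wrap
#' around the ring or are `NA`.
#'
#' @param bb a [backbone()].
#' @return a [torsion_set()].
#' @export
backbone_to_torsions <- function(bb) {
  L <- length(bb)
  phi <- psi <- omega <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    ip <- if (i > 1) i - 1 else if (bb$cyclic) L else NA
    if (!is.na(ip)) {
      phi[i] <- dihedral(bb$C[ip, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
    nx <- if (i < L) i + 1 else if (bb$cyclic) 1 else NA
    if (!is.na(nx)) {
      psi[i] <- dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[nx, ])
      omega[i] <- dihedral(bb$CA[i, ], bb$C[i, ], bb$N[nx, ], bb$CA[nx, ])
    }
  }
  torsion_set(phi, psi, omega, cyclic = bb$cyclic)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference`; a reflection is never applied (the smallest
#' singular direction is sign-corrected when the determinant is negative).
#'
#' @param mobile,reference n x 3 point matrices with equal n >= 3.
#' @return an object of class `superposition`: fields `rotation` (3 x 3
#'   proper rotation acting on column vectors), `translation` (length-3)
#'   and `rmsd` (Angstrom). The fitted points are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference) {
  if (!is.matrix(mobile) || !is.matrix(reference) ||
      ncol(mobile) != 3 || ncol(reference) != 3) {
    abort_invalid("point sets must be n x 3 matrices")
  }
  if (nrow(mobile) != nrow(reference)) abort_invalid("point counts differ")
  if (nrow(mobile) < 3) abort_invalid("need at least 3 points")
  if (!all(is.finite(mobile)) || !all(is.finite(reference))) {
    abort_invalid("non-finite coordinates")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm)
  R <- sweep(reference, 2, cr)
  H <- t(M) %*% R
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cr - rot %*% cm), rmsd = rmsd),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to a point matrix
#' @param sp a `superposition` from [kabsch_superpose()].
#' @param points an n x 3 matrix.
#' @return the transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, points) {
  sweep(points %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Backbone heavy-atom RMSD after optimal superposition
#'
#' Superposes the selected atoms of all residues with [kabsch_superpose()]
#' and returns the resulting RMSD. Residue correspondence follows the
#' stored numbering; no cyclic-permutation search is performed.
#'
#' @param pred,ref [backbone()]s of equal length.
#' @param atoms atom subset; default all four backbone heavy atoms.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(pred, ref, atoms = BACKBONE_ATOMS) {
  if (length(pred) != length(ref)) abort_invalid("backbone lengths differ")
  if (length(atoms) < 1) abort_invalid("atom set must be non-empty")
  kabsch_superpose(
    backbone_atom_matrix(pred, atoms),
    backbone_atom_matrix(ref, atoms)
  )$rmsd
}

#' Head-to-tail closure diagnostics
#'
#' Quantifies how far a backbone is from an ideal head-to-tail amide bond:
#' the C(L)-N(1) bond-length deviation, the larger of the two flanking
#' bond-angle deviations, and the deviation of the wrap omega from the
#' trans value of 180 degrees.
#'
#' @param bb a [backbone()].
#' @param geom an [ideal_geometry()].
#' @return a list with `bond_dev` (Angstrom), `angle_dev` and `omega_dev`
#'   (degrees).
#' @export
closure_residual <- function(bb, geom = ideal_geometry()) {
  L <- length(bb)
  bond_dev <- abs(vnorm(bb$C[L, ] - bb$N[1, ]) - geom$c_n)
  a1 <- abs(bond_angle(bb$CA[L, ], bb$C[L, ], bb$N[1, ]) - geom$ca_c_n)
  a2 <- abs(bond_angle(bb$C[L, ], bb$N[1, ], bb$CA[1, ]) - geom$c_n_ca)
  om <- dihedral(bb$CA[L, ], bb$C[L, ], bb$N[1, ], bb$CA[1, ])
  list(
    bond_dev = bond_dev,
    angle_dev = max(a1, a2),
    omega_dev = abs(wrap_angle(om - 180))
  )
}

#' Place backbone amide hydrogens
#'
#' Standard amide geometry: H at 1.01 Angstrom from N, in the
#' C(prev)-N-CA plane, along the bisector of the external angle. For a
#' cyclic backbone residue 1's preceding carbonyl is residue L's; for a
#' linear backbone residue 1 has no amide H (`NA` row).
#'
#' @param bb a [backbone()].
#' @return an L x 3 matrix of H coordinates (Angstrom).
#' @export
place_amide_hydrogens <- function(bb) {
  L <- length(bb)
  prev <- c(L, seq_len(L - 1L))
  u1 <- bb$N - bb$C[prev, , drop = FALSE]
  u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- bb$N - bb$CA
  u2 <- u2 / sqrt(rowSums(u2^2))
  s <- u1 + u2
  s <- s / sqrt(rowSums(s^2))
  H <- bb$N + 1.01 * s
  if (!bb$cyclic) H[1, ] <- NA_real_
  H
}
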