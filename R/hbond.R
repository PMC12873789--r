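# Backbone-backbone hydrogen-bond detection and counting on cyclic
# backbones; implements the length-dependent dataset filter.

#' Geometric hydrogen-bond criteria
#'
#' A donor amide N-H and an acceptor carbonyl O form a backbone hydrogen
#' bond when the H...O distance is at most `max_dist`, the N-H...O angle at
#' the hydrogen is at least `min_angle` (180 = linear), and the residues
#' are at least `min_sep` apart around the ring.
#'
#' @param max_dist maximum H...O distance in Angstrom (default 2.5).
#' @param min_angle minimum N-H...O angle in degrees (default 120).
#' @param min_sep minimum cyclic sequence separation (default 2).
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_dist = 2.5, min_angle = 120, min_sep = 2) {
  if (max_dist <= 0) abort_invalid("max_dist must be positive")
  if (min_angle <= 0 || min_angle > 180) abort_invalid("min_angle must be in (0, 180]")
  if (min_sep < 1) abort_invalid("min_sep must be >= 1")
  structure(
    list(max_dist = max_dist, min_angle = min_angle, min_sep = min_sep),
    class = "hbond_criteria"
  )
}

# shared detection core (plain list output; the exported wrapper adds
# the tibble)
hbond_core <- function(bb, criteria) {
  L <- length(bb)
  H <- place_amide_hydrogens(bb)
  # all donor x acceptor geometry at once
  dx <- outer(H[, 1], bb$O[, 1], `-`)
  dy <- outer(H[, 2], bb$O[, 2], `-`)
  dz <- outer(H[, 3], bb$O[, 3], `-`)
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  nh <- bb$N - H
  nhlen <- sqrt(rowSums(nh^2))
  # cos of N-H...O angle at H: (N-H).(O-H) / (|N-H| |O-H|)
  dotp <- -(nh[, 1] * dx + nh[, 2] * dy + nh[, 3] * dz)
  ang <- acos(pmin(pmax(dotp / (nhlen * dist), -1), 1)) * 180 / pi
  idx <- abs(outer(seq_len(L), seq_len(L), `-`))
  sep <- pmin(idx, L - idx)
  ok <- !is.na(dist) & dist <= criteria$max_dist & ang >= criteria$min_angle &
    sep >= criteria$min_sep & is.finite(dist)
  donors <- acceptors <- integer(0)
  dists <- angles <- numeric(0)
  for (i in seq_len(L)) {
    js <- which(ok[i, ])
    if (!length(js)) next
    j <- js[which.min(dist[i, js])]
    donors <- c(donors, i)
    acceptors <- c(acceptors, j)
    dists <- c(dists, dist[i, j])
    angles <- c(angles, ang[i, j])
  }
  list(donor = donors, acceptor = acceptors, dist = dists, angle = angles)
}

#' Detect backbone-backbone hydrogen bonds
#'
#' Amide hydrogens are placed with [place_amide_hydrogens()]. Every donor
#' reports at most one bond, to its closest qualifying acceptor; an
#' acceptor may serve several donors. Sequence separation is measured
#' around the ring: `min(|i - j|, L - |i - j|)`.
#'
#' @param bb a [backbone()].
#' @param criteria an [hbond_criteria()].
#' @return a tibble with columns `donor`, `acceptor` (residue indices,
#'   1-based), `dist` (H...O, Angstrom) and `angle` (N-H...O, degrees),
#'   sorted by donor.
#' @export
detect_backbone_hbonds <- function(bb, criteria = hbond_criteria()) {
  tibble::as_tibble(hbond_core(bb, criteria))
}

#' Count backbone hydrogen bonds
#'
#' @inheritParams detect_backbone_hbonds
#' @return integer bond count.
#' @export
hbond_count <- function(bb, criteria = hbond_criteria()) {
  length(hbond_core(bb, criteria)$donor)
}

#' Length-dependent minimum hydrogen-bond count
#'
#' The dataset filter requires at least 1, 2 and 3 backbone hydrogen bonds
#' for 6-, 8- and 10-residue macrocycles. Other lengths extrapolate as
#' `ceiling((L - 4) / 2)`, bounded below by 1.
#'
#' @param length residue count.
#' @return integer minimum count.
#' @export
default_min_hbonds <- function(length) {
  known <- c(`6` = 1L, `8` = 2L, `10` = 3L)
  key <- as.character(length)
  if (key %in% names(known)) return(known[[key]])
  max(1L, as.integer(ceiling((length - 4) / 2)))
}
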