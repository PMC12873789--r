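# Iterative head-to-tail ring closure by cyclic coordinate descent (CCD).

# Atom index helpers for the flat (3L + 3) x 3 chain matrix holding
# N, CA, C of residues 1..L plus a virtual next residue's N, CA, C.
chain_idx <- function(res, atom) (res - 1L) * 3L + c(N = 1L, CA = 2L, C = 3L)[atom]

# Build the N/CA/C chain plus virtual closure atoms from torsions.
build_chain <- function(torsions, geom) {
  L <- length(torsions)
  A <- matrix(0, 3L * L + 3L, 3)
  th <- deg2rad(geom$n_ca_c)
  A[1, ] <- c(0, 0, 0)
  A[2, ] <- c(geom$n_ca, 0, 0)
  A[3, ] <- A[2, ] + geom$ca_c * c(-cos(th), sin(th), 0)
  phi_next <- c(torsions$phi[-1], torsions$phi[1])
  for (i in seq_len(L)) {
    k <- 3L * (i - 1L)
    A[k + 4L, ] <- place_atom(A[k + 1L, ], A[k + 2L, ], A[k + 3L, ],
                              geom$c_n, geom$ca_c_n, torsions$psi[i])
    A[k + 5L, ] <- place_atom(A[k + 2L, ], A[k + 3L, ], A[k + 4L, ],
                              geom$n_ca, geom$c_n_ca, torsions$omega[i])
    A[k + 6L, ] <- place_atom(A[k + 3L, ], A[k + 4L, ], A[k + 5L, ],
                              geom$ca_c, geom$n_ca_c, phi_next[i])
  }
  A
}

# Assemble a backbone object from the chain matrix of a closed ring,
# placing carbonyl O atoms in the CA-C-N(next) plane.
chain_to_backbone <- function(A, L, geom, id = "closed") {
  N <- A[seq(1L, 3L * L, by = 3L), , drop = FALSE]
  CA <- A[seq(2L, 3L * L, by = 3L), , drop = FALSE]
  C <- A[seq(3L, 3L * L, by = 3L), , drop = FALSE]
  O <- matrix(0, L, 3)
  for (i in seq_len(L)) {
    nx <- if (i < L) i + 1L else 1L
    O[i, ] <- place_atom(N[nx, ], CA[i, ], C[i, ], geom$c_o, geom$ca_c_o, 180)
  }
  backbone(N, CA, C, O, cyclic = TRUE, id = id)
}

# Closure residual measured directly on the chain matrix.
chain_closure_residual <- function(A, L, geom) {
  CL <- A[chain_idx(L, "C"), ]
  N1 <- A[1, ]
  CA1 <- A[2, ]
  CAL <- A[chain_idx(L, "CA"), ]
  list(
    bond_dev = abs(vnorm(CL - N1) - geom$c_n),
    angle_dev = max(
      abs(bond_angle(CAL, CL, N1) - geom$ca_c_n),
      abs(bond_angle(CL, N1, CA1) - geom$c_n_ca)
    ),
    omega_dev = abs(wrap_angle(dihedral(CAL, CL, N1, CA1) - 180))
  )
}

# Adjustable torsions for a pivot mode, as a 2-column matrix
# (residue, angle) with angle 0 = phi, 1 = psi. The wrap dihedral phi(1)
# is never adjusted (it is not a chain-building degree of freedom).
closure_torsion_table <- function(L, pivots = c("all", "spread3")) {
  pivots <- match.arg(pivots)
  res <- if (pivots == "all") seq_len(L) else closure_pivots(L)
  out <- matrix(0L, 0, 2)
  for (p in res) {
    if (p > 1L) out <- rbind(out, c(p, 0L))
    out <- rbind(out, c(p, 1L))
  }
  out
}

#' Default spread pivot residues
#'
#' Three residues spread evenly around the ring (always including the last
#' residue), for the `"spread3"` pivot mode of [close_ring()].
#'
#' @param length residue count.
#' @return integer vector of three residue indices.
#' @export
closure_pivots <- function(length) {
  unique(ceiling(seq(2, length, length.out = 3)))
}

# Pure-R reference implementation of the CCD loop (same algorithm as the
# compiled engine; kept for cross-checking).
ccd_close_r <- function(A, L, tors, tol_b, tol_a, max_sweeps, max_step, geom) {
  n <- nrow(A)
  res <- chain_closure_residual(A, L, geom)
  ok <- function(r) r$bond_dev <= tol_b && r$angle_dev <= tol_a
  sweeps <- 0L
  while (!ok(res) && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    for (t in seq_len(nrow(tors))) {
      p <- tors[t, 1]
      i0 <- if (tors[t, 2] == 0L) chain_idx(p, "N") else chain_idx(p, "CA")
      i1 <- i0 + 1L
      origin <- A[i1, ]
      k <- unit(A[i1, ] - A[i0, ])
      a <- 0
      b <- 0
      for (m in (n - 2L):n) {
        mrel <- A[m, ] - origin
        r <- mrel - sum(mrel * k) * k
        f <- A[m - (n - 3L), ] - origin
        f <- f - sum(f * k) * k
        a <- a + sum(f * r)
        b <- b + sum(f * cross3(k, r))
      }
      theta <- max(-max_step, min(max_step, atan2(b, a)))
      if (abs(theta) < 1e-12) next
      R <- rotation_about_axis(k, theta)
      move <- (i1 + 1L):n
      A[move, ] <- sweep(sweep(A[move, , drop = FALSE], 2, origin) %*% t(R), 2, origin, `+`)
    }
    res <- chain_closure_residual(A, L, geom)
  }
  list(chain = A, sweeps = sweeps, bond_dev = res$bond_dev,
       angle_dev = res$angle_dev, omega_dev = res$omega_dev, success = ok(res))
}

#' Close a head-to-tail ring by cyclic coordinate descent
#'
#' Adjusts backbone phi/psi torsions (omega is never touched) so that the
#' chain meets its own first residue with an ideal C(L)-N(1) amide bond.
#' A virtual copy of residue 1's N/CA/C is continued past residue L; CCD
#' sweeps rotate each adjustable torsion by the step-capped angle that
#' best superposes the virtual atoms onto the real ones, until the closure
#' residual is within tolerance or the sweep budget is spent.
#'
#' By default every residue's phi/psi participates, so the closure
#' correction is spread thinly around the ring and accepted conformations
#' stay close to their Ramachandran-sampled torsions. The `"spread3"`
#' mode restricts adjustment to three evenly spaced pivot residues.
#'
#' @param torsions a fully defined cyclic [torsion_set()].
#' @param geom an [ideal_geometry()].
#' @param config a [sampler_config()]; supplies tolerances, the sweep
#'   budget, the per-update step cap and the pivot mode.
#' @param engine `"cpp"` (compiled inner loop, default) or `"r"` (pure-R
#'   reference implementation of the same algorithm).
#' @return a list of class `closure_result`: `success` (logical),
#'   `torsions` (re-measured from the closed coordinates, wrap angles
#'   included; the unchanged input on failure), `backbone` (the closed
#'   [backbone()], `NULL` on failure), `sweeps`, `residual` (as
#'   [closure_residual()]).
#' @export
close_ring <- function(torsions, geom = ideal_geometry(),
                       config = sampler_config(length(torsions)),
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  L <- length(torsions)
  if (anyNA(c(torsions$phi, torsions$psi, torsions$omega))) {
    abort_invalid("all torsions must be defined for ring closure")
  }
  tors <- closure_torsion_table(L, config$pivots)
  A <- build_chain(torsions, geom)
  max_step <- deg2rad(config$closure_max_step)
  r <- if (engine == "cpp") {
    .ccd_close_cpp(A, L, as.integer(tors[, 1]), as.integer(tors[, 2]),
                   config$closure_tolerance_bond, config$closure_tolerance_angle,
                   config$max_closure_iterations, max_step,
                   geom$c_n, geom$ca_c_n, geom$c_n_ca)
  } else {
    ccd_close_r(A, L, tors, config$closure_tolerance_bond,
                config$closure_tolerance_angle, config$max_closure_iterations,
                max_step, geom)
  }
  bb <- if (r$success) chain_to_backbone(r$chain, L, geom) else NULL
  structure(
    list(
      success = r$success,
      torsions = if (r$success) backbone_to_torsions(bb) else torsions,
      backbone = bb,
      sweeps = r$sweeps,
      residual = list(bond_dev = r$bond_dev, angle_dev = r$angle_dev,
                      omega_dev = r$omega_dev),
      pivots = config$pivots
    ),
    class = "closure_result"
  )
}

#' Ramachandran-restrained ring closure
#'
#' The sampler's workhorse. Each residue is assigned the maximum-posterior
#' basin of its sampled torsions; the routine then runs a projected
#' Gauss-Newton descent on the closure manifold, tethering torsions to
#' their assigned basin centers and backbone bond angles to ideal geometry
#' (tight spread, so accepted conformations carry only the few degrees of
#' angular strain real macrocycles do). Closure is maintained by Newton
#' restoration of the virtual end triad after every step. If the sampled
#' start does not converge, a small number of restarts jittered around the
#' assigned basin centers are tried before reporting failure; failures
#' mean the sampled basin assignment admits no closed allowed ring.
#'
#' @inheritParams close_ring
#' @param model a [rama_model()].
#' @param e_target energy level accepted conformations must reach;
#'   defaults to 90 percent of the config's `rama_cutoff` so they sit
#'   strictly inside the filter region.
#' @param restarts jittered restarts after the sampled start (default 3).
#' @return a `closure_result` as for [close_ring()], with an extra
#'   `angle_strain` field (largest bond-angle deviation from ideal, in
#'   degrees).
#' @export
close_ring_rama <- function(torsions, model = rama_model(),
                            geom = ideal_geometry(),
                            config = sampler_config(length(torsions)),
                            e_target = 0.9 * config$rama_cutoff,
                            restarts = 3) {
  L <- length(torsions)
  if (anyNA(c(torsions$phi, torsions$psi, torsions$omega))) {
    abort_invalid("all torsions must be defined for ring closure")
  }
  b <- model$basins
  post <- sapply(seq_len(nrow(b)), function(k) {
    b$weight[k] * wrapped_density(torsions$phi, b$phi[k], b$spread[k]) *
      wrapped_density(torsions$psi, b$psi[k], b$spread[k])
  })
  assign <- max.col(matrix(post, nrow = L))
  run <- function(tt) {
    A <- .build_chain_cpp(tt$phi, tt$psi, tt$omega, geom$n_ca, geom$ca_c,
                          geom$c_n, geom$n_ca_c, geom$ca_c_n, geom$c_n_ca)
    .ring_relax_cpp(
      A, L,
      config$closure_tolerance_bond, config$closure_tolerance_angle,
      max_iter = as.integer(config$max_closure_iterations),
      step_cap_deg = 5,
      basins = cbind(b$phi, b$psi, b$spread, b$weight),
      assign = as.integer(assign),
      p_max = model$p_max, e_target = e_target,
      sigma_angle = config$angle_flex_sigma,
      stall_limit = as.integer(config$stall_limit %||% 25L),
      n_ca_c = geom$n_ca_c, ca_c_n = geom$ca_c_n, c_n_ca = geom$c_n_ca,
      c_n = geom$c_n, ca_c_nn = geom$ca_c_n, c_n_caa = geom$c_n_ca
    )
  }
  r <- run(torsions)
  tries <- 0L
  while (!r$success && tries < restarts) {
    tries <- tries + 1L
    jit <- torsion_set(
      b$phi[assign] + stats::rnorm(L, 0, 15),
      b$psi[assign] + stats::rnorm(L, 0, 15),
      torsions$omega, cyclic = TRUE
    )
    r <- run(jit)
  }
  bb <- NULL
  tors_out <- torsions
  if (r$success) {
    bb <- chain_to_backbone(r$chain, L, geom)
    seam <- dihedral(bb$CA[L, ], bb$C[L, ], bb$N[1, ], bb$CA[1, ])
    tors_out <- torsion_set(r$phi, r$psi,
                            c(torsions$omega[-L], seam), cyclic = TRUE)
  }
  structure(
    list(
      success = r$success,
      torsions = tors_out,
      backbone = bb,
      sweeps = r$sweeps,
      residual = list(bond_dev = r$bond_dev, angle_dev = r$angle_dev,
                      omega_dev = r$omega_dev),
      angle_strain = r$angle_strain,
      pivots = config$pivots
    ),
    class = "closure_result"
  )
}
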