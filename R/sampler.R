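# Ensemble generation: Ramachandran-biased torsion sampling, CCD ring
# closure, Ramachandran-energy and hydrogen-bond filtering.

#' Sampler configuration
#'
#' @param length residue count (>= 3).
#' @param n_target requested ensemble size.
#' @param rama_cutoff per-residue Ramachandran energy threshold (default 2).
#' @param min_hbonds minimum backbone hydrogen bonds; `NULL` uses the
#'   length-dependent default of [default_min_hbonds()].
#' @param closure_tolerance_bond accepted C(L)-N(1) bond-length deviation
#'   in Angstrom (default 0.05).
#' @param closure_tolerance_angle accepted closure bond-angle deviation in
#'   degrees (default 5).
#' @param max_closure_iterations CCD sweep budget per attempt (default 100).
#' @param closure_max_step per-update torsion step cap in degrees
#'   (default 10); spreads the closure correction over many torsions.
#' @param angle_flex_sigma tether spread for backbone bond-angle flexing
#'   during Ramachandran-restrained closure, in degrees (default 2.5);
#'   accepted conformations carry at most a few degrees of angular strain,
#'   as real macrocycles do.
#' @param stall_limit iterations without worst-residue improvement before
#'   one closure-relax run is abandoned (default 25).
#' @param pivots `"all"` (every residue's phi/psi adjustable, default) or
#'   `"spread3"` (three evenly spaced pivot residues).
#' @param attempt_cap total sampling attempts before giving up; default
#'   `50 * n_target`.
#' @param seed integer master seed for the ensemble.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(length, n_target = 100, rama_cutoff = 2,
                           min_hbonds = NULL,
                           closure_tolerance_bond = 0.05,
                           closure_tolerance_angle = 5,
                           max_closure_iterations = 100,
                           closure_max_step = 10,
                           angle_flex_sigma = 2.5,
                           stall_limit = 25,
                           pivots = c("all", "spread3"),
                           attempt_cap = 50 * n_target, seed = 1) {
  pivots <- match.arg(pivots)
  if (length < 3) abort_invalid("length must be >= 3")
  if (n_target < 1) abort_invalid("n_target must be >= 1")
  if (rama_cutoff < 0) abort_invalid("rama_cutoff must be >= 0")
  if (closure_tolerance_bond <= 0 || closure_tolerance_angle <= 0) {
    abort_invalid("closure tolerances must be positive")
  }
  structure(
    list(
      length = as.integer(length), n_target = as.integer(n_target),
      rama_cutoff = rama_cutoff,
      min_hbonds = if (is.null(min_hbonds)) default_min_hbonds(length) else as.integer(min_hbonds),
      closure_tolerance_bond = closure_tolerance_bond,
      closure_tolerance_angle = closure_tolerance_angle,
      max_closure_iterations = as.integer(max_closure_iterations),
      closure_max_step = closure_max_step,
      angle_flex_sigma = angle_flex_sigma,
      stall_limit = as.integer(stall_limit),
      pivots = pivots,
      attempt_cap = as.integer(attempt_cap),
      seed = as.integer(seed)
    ),
    class = "sampler_config"
  )
}

#' Generate a filtered ensemble of closed cyclic backbones
#'
#' Repeats sample -> close -> Ramachandran filter -> hydrogen-bond filter
#' until `n_target` conformations are accepted or the attempt cap is hit.
#' Every returned backbone is ring-closed within tolerance, has all
#' per-residue Ramachandran energies at or below the cutoff and at least
#' `min_hbonds` backbone hydrogen bonds. Deterministic given the seed.
#'
#' The Ramachandran filter is applied to the torsions re-measured from the
#' closed conformation, so accepted ensembles are filtered on what they
#' actually are, not on the pre-closure sample.
#'
#' @param config a [sampler_config()].
#' @param model a [rama_model()].
#' @param geom an [ideal_geometry()].
#' @param criteria an [hbond_criteria()].
#' @return a list of class `backbone_ensemble`: `backbones` (list of
#'   [backbone()]), `torsions` (list of [torsion_set()]), and `stats`
#'   (one-row tibble: attempts, accepted, closure_failures, rama_rejects,
#'   hbond_rejects).
#' @export
generate_ensemble <- function(config, model = rama_model(),
                              geom = ideal_geometry(),
                              criteria = hbond_criteria()) {
  L <- config$length
  run <- function() {
    backbones <- list()
    torsions <- list()
    attempts <- 0L
    closure_failures <- 0L
    rama_rejects <- 0L
    hbond_rejects <- 0L
    while (length(backbones) < config$n_target && attempts < config$attempt_cap) {
      attempts <- attempts + 1L
      t0 <- sample_torsions(L, model)
      cl <- close_ring_rama(t0, model, geom, config)
      if (!cl$success) {
        closure_failures <- closure_failures + 1L
        next
      }
      tc <- cl$torsions
      if (any(rama_energy(tc$phi, tc$psi, model) > config$rama_cutoff)) {
        rama_rejects <- rama_rejects + 1L
        next
      }
      bb <- cl$backbone
      bb$id <- sprintf("L%d_seed%d_%04d", L, config$seed, length(backbones) + 1L)
      if (hbond_count(bb, criteria) < config$min_hbonds) {
        hbond_rejects <- hbond_rejects + 1L
        next
      }
      backbones[[length(backbones) + 1L]] <- bb
      torsions[[length(torsions) + 1L]] <- tc
    }
    if (length(backbones) < config$n_target) {
      warning(sprintf(
        "attempt cap (%d) reached: %d of %d requested conformations accepted",
        config$attempt_cap, length(backbones), config$n_target
      ))
    }
    stats <- tibble::tibble(
      attempts = attempts, accepted = length(backbones),
      closure_failures = closure_failures, rama_rejects = rama_rejects,
      hbond_rejects = hbond_rejects
    )
    structure(
      list(backbones = backbones, torsions = torsions, stats = stats),
      class = "backbone_ensemble"
    )
  }
  withr::with_seed(config$seed, run())
}

#' @export
print.backbone_ensemble <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<backbone_ensemble: %d accepted / %d attempts (closure fail %d, rama %d, hbond %d)>\n",
    s$accepted, s$attempts, s$closure_failures, s$rama_rejects, s$hbond_rejects
  ))
  invisible(x)
}
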