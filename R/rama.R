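# Ramachandran basin mixture: the sampling density and pseudo-energy used
# to bias and filter backbone torsion sampling.

#' Default Ramachandran basin table
#'
#' Four basins of L-alpha-amino-acid backbone dihedral space: right-handed
#' alpha helix, beta strand, polyproline II and left-handed alpha. Centers
#' and spreads in degrees; weights sum to 1. The 25-degree spread makes
#' the energy-below-2 region cover roughly a sixth of the plane, close to
#' a real alanine Ramachandran map; much tighter spreads leave almost no
#' ring-closable conformations inside the allowed region.
#'
#' @return a data.frame with columns `basin`, `phi`, `psi`, `spread`,
#'   `weight`.
#' @export
default_rama_basins <- function() {
  data.frame(
    basin = c("alphaR", "beta", "ppII", "alphaL"),
    phi = c(-63, -120, -75, 60),
    psi = c(-41, 130, 150, 45),
    spread = c(25, 25, 25, 25),
    weight = c(0.35, 0.30, 0.25, 0.10)
  )
}

# Wrapped-normal density in degrees, truncated to one wrap either side.
# Vectorised over `x`.
wrapped_density <- function(x, mu, sigma) {
  d <- wrap_angle(x - mu)
  (stats::dnorm(d, 0, sigma) + stats::dnorm(d + 360, 0, sigma) +
    stats::dnorm(d - 360, 0, sigma))
}

#' Build a Ramachandran mixture model
#'
#' The joint (phi, psi) density is a weighted mixture of independent
#' wrapped-normal factors, one basin per row of `basins`. The pseudo-energy
#' is the max-normalised negative log density, so the most probable point
#' has energy 0 and energy is >= 0 everywhere (the normaliser is located
#' numerically on a dense grid over both angles).
#'
#' @param basins a data.frame like [default_rama_basins()]; weights are
#'   normalised to sum to 1.
#' @return an object of class `rama_model`.
#' @export
rama_model <- function(basins = default_rama_basins()) {
  stopifnot(all(c("phi", "psi", "spread", "weight") %in% names(basins)))
  if (any(basins$weight <= 0) || any(basins$spread <= 0)) {
    abort_invalid("basin weights and spreads must be positive")
  }
  basins$weight <- basins$weight / sum(basins$weight)
  m <- structure(list(basins = basins, p_max = 1), class = "rama_model")
  grid <- seq(-179, 180, by = 2)
  centers_phi <- c(basins$phi, rep(grid, times = length(grid)))
  centers_psi <- c(basins$psi, rep(grid, each = length(grid)))
  m$p_max <- max(rama_density(centers_phi, centers_psi, m))
  m
}

# Mixture density, vectorised over phi/psi.
rama_density <- function(phi, psi, model) {
  b <- model$basins
  p <- 0
  for (k in seq_len(nrow(b))) {
    p <- p + b$weight[k] *
      wrapped_density(phi, b$phi[k], b$spread[k]) *
      wrapped_density(psi, b$psi[k], b$spread[k])
  }
  p
}

#' Ramachandran pseudo-energy
#'
#' `-log(p(phi, psi) / p_max)`, clamped at 0: zero at the density maximum,
#' non-negative and 360-degree periodic in both angles. Used to reject
#' sampled conformations whose per-residue energy exceeds a cutoff
#' (default 2 in [sampler_config()]).
#'
#' @param phi,psi angles in degrees (vectorised).
#' @param model a [rama_model()].
#' @return numeric vector of energies (dimensionless, >= 0).
#' @export
rama_energy <- function(phi, psi, model = rama_model()) {
  pmax(0, -log(rama_density(phi, psi, model) / model$p_max))
}

#' Sample a torsion set from the basin mixture
#'
#' Each residue's (phi, psi) is drawn independently: a basin by weight,
#' then a wrapped-normal perturbation around its center. All omega angles
#' are set to 180 (trans). Uses the current RNG state unless `seed` is
#' given.
#'
#' @param length residue count.
#' @param model a [rama_model()].
#' @param seed optional integer; if given, sampling is wrapped in
#'   [withr::with_seed()] for reproducibility.
#' @return a cyclic [torsion_set()].
#' @export
sample_torsions <- function(length, model = rama_model(), seed = NULL) {
  draw <- function() {
    b <- model$basins
    ks <- sample.int(nrow(b), length, replace = TRUE, prob = b$weight)
    phi <- wrap_angle(stats::rnorm(length, b$phi[ks], b$spread[ks]))
    psi <- wrap_angle(stats::rnorm(length, b$psi[ks], b$spread[ks]))
    torsion_set(phi, psi, rep(180, length), cyclic = TRUE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
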