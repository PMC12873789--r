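# Shared lazy fixtures. Everything is generated in code under fixed
# seeds; expensive objects are cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

ring_fixture <- function(L) cached(paste0("ring", L), make_ideal_ring(L))

# small filtered ensembles per length (hydrogen-bond filter active)
ensemble_fixture <- function(L, n = 25, seed = 3) {
  cached(sprintf("ens_%d_%d_%d", L, n, seed), {
    suppressWarnings(generate_ensemble(sampler_config(L, n_target = n, seed = seed)))
  })
}

# unfiltered closed rings (no hydrogen-bond requirement), cheaper
closed_rings_fixture <- function(L, n = 10, seed = 7) {
  cached(sprintf("rings_%d_%d_%d", L, n, seed), {
    suppressWarnings(
      generate_ensemble(sampler_config(L, n_target = n, min_hbonds = 0, seed = seed))
    )$backbones
  })
}

tiny_model_config <- function() {
  model_config(hidden_dim = 16, enc_layers = 2, dec_layers = 2, n_rbf = 4, d_max = 8)
}

tiny_params <- function() cached("tiny_params", init_params(tiny_model_config(), seed = 7))

# ---- independent oracles -------------------------------------------------

# Quaternion (Horn) superposition oracle: RMSD from the largest eigenvalue
# of the 4x4 quaternion characteristic matrix; fully independent of the
# SVD-based production path.
quaternion_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm)
  R <- sweep(reference, 2, cr)
  S <- t(M) %*% R
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(M^2) + sum(R^2) - 2 * lambda) / nrow(M)
  sqrt(max(0, msd))
}

# Brute-force hydrogen-bond scan: direct double loop over all donor /
# acceptor pairs, one best acceptor per donor.
brute_force_hbonds <- function(bb, criteria = hbond_criteria()) {
  L <- length(bb)
  H <- place_amide_hydrogens(bb)
  out <- NULL
  for (i in seq_len(L)) {
    if (anyNA(H[i, ])) next
    best <- NULL
    for (j in seq_len(L)) {
      sep <- min(abs(i - j), L - abs(i - j))
      if (sep < criteria$min_sep) next
      d <- sqrt(sum((H[i, ] - bb$O[j, ])^2))
      if (d > criteria$max_dist) next
      v1 <- bb$N[i, ] - H[i, ]
      v2 <- bb$O[j, ] - H[i, ]
      ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(min(1, max(-1, ca))) * 180 / pi
      if (ang < criteria$min_angle) next
      if (is.null(best) || d < best$d) best <- list(j = j, d = d)
    }
    if (!is.null(best)) out <- rbind(out, c(i, best$j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# rotate residue indexing of a backbone: new residue 1 is old residue s
reindex_backbone <- function(bb, s) {
  L <- length(bb)
  idx <- ((seq_len(L) + s - 2L) %% L) + 1L
  backbone(bb$N[idx, , drop = FALSE], bb$CA[idx, , drop = FALSE],
           bb$C[idx, , drop = FALSE], bb$O[idx, , drop = FALSE],
           cyclic = bb$cyclic, id = paste0(bb$id, "_shift", s))
}

random_rigid_transform <- function(bb, seed = NULL) {
  run <- function() {
    ax <- stats::rnorm(3)
    R <- cyclicdesign:::rotation_about_axis(ax, stats::runif(1, 0, 2 * pi))
    t <- stats::rnorm(3, 0, 10)
    out <- bb
    for (a in c("N", "CA", "C", "O")) {
      out[[a]] <- sweep(bb[[a]] %*% t(R), 2, t, `+`)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

random_sequence <- function(L) paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")

# short aliases for internal helpers used throughout the tests
wrap_angle <- cyclicdesign:::wrap_angle
cross3 <- cyclicdesign:::cross3
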