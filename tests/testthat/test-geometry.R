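test_that("chain building starts in the canonical frame with ideal bonds", {
  g <- ideal_geometry()
  t <- sample_torsions(5, seed = 1)
  bb <- torsions_to_backbone(t, g)
  expect_equal(bb$N[1, ], c(0, 0, 0))
  expect_equal(bb$CA[1, ], c(g$n_ca, 0, 0))
  expect_equal(bb$C[1, 3], 0, tolerance = 1e-12)
  # every internal C(i)-N(i+1) bond at the ideal length
  for (i in 1:4) {
    expect_equal(sqrt(sum((bb$C[i, ] - bb$N[i + 1, ])^2)), g$c_n,
                 tolerance = 1e-6)
  }
  expect_error(torsions_to_backbone(sample_torsions(2, seed = 1)),
               "at least 3")
})

test_that("torsion -> coordinates -> torsion round trip is the identity", {
  g <- ideal_geometry()
  for (k in 1:100) {
    L <- sample(4:10, 1)
    t <- sample_torsions(L, seed = 1000 + k)
    t$phi <- wrap_angle(t$phi + stats::runif(L, -180, 180))
    t$psi <- wrap_angle(t$psi + stats::runif(L, -180, 180))
    bb <- torsions_to_backbone(t, g)
    bb$cyclic <- FALSE  # measure only sequentially-placed dihedrals
    t2 <- backbone_to_torsions(bb)
    expect_true(is.na(t2$phi[1]) && is.na(t2$psi[L]) && is.na(t2$omega[L]))
    expect_lt(max(abs(wrap_angle(t2$phi[-1] - t$phi[-1]))), 1e-4)
    expect_lt(max(abs(wrap_angle(t2$psi[-L] - t$psi[-L]))), 1e-4)
    expect_lt(max(abs(wrap_angle(t2$omega[-L] - t$omega[-L]))), 1e-4)
  }
})

test_that("linear terminal dihedrals are flagged undefined", {
  bb <- torsions_to_backbone(sample_torsions(4, seed = 2))
  bb$cyclic <- FALSE
  t <- backbone_to_torsions(bb)
  expect_true(is.na(t$phi[1]))
  expect_true(is.na(t$psi[4]))
  expect_true(is.na(t$omega[4]))
  expect_false(anyNA(t$phi[-1]))
})

test_that("the symmetric ring fixture measures all-trans omega", {
  ring <- ring_fixture(6)
  t <- backbone_to_torsions(ring)
  expect_lt(max(abs(wrap_angle(t$omega - 180))), 1e-3)
})

test_that("Kabsch superposition is exact on rigid copies and symmetric", {
  set.seed(4)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  R <- cyclicdesign:::rotation_about_axis(c(1, 2, -1), 37 * pi / 180)
  B <- sweep(A %*% t(R), 2, c(5, -2, 9), `+`)
  expect_lt(kabsch_superpose(B, A)$rmsd, 1e-8)
  # symmetry and fitted-point consistency
  C <- A + matrix(rnorm(30, 0, 0.5), 10, 3)
  sp <- kabsch_superpose(A, C)
  expect_equal(sp$rmsd, kabsch_superpose(C, A)$rmsd, tolerance = 1e-8)
  fitted <- apply_superposition(sp, A)
  expect_equal(sqrt(mean(rowSums((fitted - C)^2))), sp$rmsd, tolerance = 1e-10)
  # proper rotation, never a reflection
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  expect_equal(t(sp$rotation) %*% sp$rotation, diag(3), tolerance = 1e-8)
  expect_error(kabsch_superpose(A, A[1:5, ]), "count")
  expect_error(kabsch_superpose(A[1:2, ], C[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches the quaternion eigenvalue oracle", {
  set.seed(9)
  for (k in 1:1000) {
    n <- sample(3:12, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("backbone RMSD handles identity, translation and displacement", {
  bb <- ring_fixture(6)
  expect_equal(backbone_rmsd(bb, bb), 0, tolerance = 1e-10)
  shifted <- bb
  for (a in c("N", "CA", "C", "O")) shifted[[a]] <- bb[[a]] + 5
  expect_lt(backbone_rmsd(shifted, bb), 1e-8)
  # single displaced CA, CA-only atom set, against the quaternion oracle
  moved <- bb
  moved$CA[3, ] <- moved$CA[3, ] + c(1, 0, 0)
  expect_equal(backbone_rmsd(moved, bb, atoms = "CA"),
               quaternion_rmsd(moved$CA, bb$CA), tolerance = 1e-8)
  expect_error(backbone_rmsd(ring_fixture(6), ring_fixture(8)), "length")
})

test_that("backbone RMSD is rigid-invariant and symmetric on random pairs", {
  for (k in 1:20) {
    bb <- closed_rings_fixture(8)[[(k %% 10) + 1]]
    tr <- random_rigid_transform(bb, seed = 100 + k)
    expect_lt(backbone_rmsd(tr, bb), 1e-8)
  }
})

test_that("closure residual reports bond, angle and omega deviations", {
  ring <- ring_fixture(8)
  cr <- closure_residual(ring)
  expect_lt(cr$bond_dev, 1e-6)
  expect_lt(cr$omega_dev, 1e-3)
  # stretch the head-to-tail bond to 3.0 A: bond_dev = 3.0 - 1.329
  g <- ideal_geometry()
  stretched <- ring
  dir <- (ring$N[1, ] - ring$C[8, ])
  dir <- dir / sqrt(sum(dir^2))
  stretched$N[1, ] <- ring$C[8, ] + 3.0 * dir
  expect_equal(closure_residual(stretched, g)$bond_dev, 3.0 - g$c_n,
               tolerance = 1e-9)
})

test_that("sampler-accepted conformations satisfy the closure tolerance", {
  for (L in c(6, 8)) {
    ens <- ensemble_fixture(L)
    devs <- vapply(ens$backbones, function(b) closure_residual(b)$bond_dev,
                   numeric(1))
    expect_true(all(devs <= sampler_config(L)$closure_tolerance_bond))
  }
})

test_that("amide hydrogens sit on the external bisector at 1.01 A", {
  bb <- closed_rings_fixture(8)[[1]]
  H <- place_amide_hydrogens(bb)
  for (i in 1:8) {
    expect_equal(sqrt(sum((H[i, ] - bb$N[i, ])^2)), 1.01, tolerance = 1e-9)
    ip <- if (i == 1) 8 else i - 1
    v1 <- bb$C[ip, ] - bb$N[i, ]
    v2 <- bb$CA[i, ] - bb$N[i, ]
    v3 <- H[i, ] - bb$N[i, ]
    # coplanar: triple product vanishes
    expect_lt(abs(sum(v3 * cyclicdesign:::cross3(v1, v2))), 1e-9)
  }
  # linear chains have no H on residue 1
  lin <- bb
  lin$cyclic <- FALSE
  expect_true(anyNA(place_amide_hydrogens(lin)[1, ]))
})

test_that("ring symmetry carries over to placed hydrogens", {
  ring <- ring_fixture(8)
  H <- place_amide_hydrogens(ring)
  # rotating indices by one and superposing backbone atoms must map
  # hydrogens onto hydrogens
  shifted <- reindex_backbone(ring, 2)
  sp <- kabsch_superpose(backbone_atom_matrix(shifted),
                         backbone_atom_matrix(ring))
  H_shift <- apply_superposition(sp, place_amide_hydrogens(shifted))
  expect_lt(max(abs(H_shift - H)), 1e-6)
})
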