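test_that("symmetric rings are equidistant, closed and truly symmetric", {
  for (L in c(6, 8)) {
    ring <- ring_fixture(L)
    cen <- colMeans(ring$CA)
    rad <- sqrt(rowSums(sweep(ring$CA, 2, cen)^2))
    expect_lt(diff(range(rad)), 1e-6)
    expect_lt(closure_residual(ring)$bond_dev, 1e-6)
    # rotating indices by one superposes onto the original
    expect_lt(backbone_rmsd(reindex_backbone(ring, 2), ring), 1e-6)
  }
  expect_error(make_ideal_ring(2), ">= 3")
})

test_that("perturbation is seeded and exact at sigma zero", {
  bb <- ring_fixture(6)
  expect_identical(perturb_backbone(bb, 0)$CA, bb$CA)
  p1 <- perturb_backbone(bb, 0.3, seed = 5)
  p2 <- perturb_backbone(bb, 0.3, seed = 5)
  expect_identical(p1$N, p2$N)
  expect_false(identical(p1$N, perturb_backbone(bb, 0.3, seed = 6)$N))
})

test_that("mean squared displacement matches 3 sigma^2", {
  bb <- ring_fixture(10)
  sigma <- 0.25
  disp2 <- c()
  for (k in 1:700) {  # 700 x 40 atoms = 28,000 displacement vectors
    p <- perturb_backbone(bb, sigma, seed = 1000 + k)
    for (a in c("N", "CA", "C", "O")) {
      disp2 <- c(disp2, rowSums((p[[a]] - bb[[a]])^2))
    }
  }
  n <- length(disp2)
  se <- sqrt(2 * 3 * sigma^4 / n)  # var of chi2_3 * sigma^2 mean
  expect_lt(abs(mean(disp2) - 3 * sigma^2), 3 * se * sqrt(2))
})

test_that("the basin-letter rule maps geometry to letters as documented", {
  # an all-alphaR torsion set labels as all-A
  t_aR <- torsion_set(rep(-63, 6), rep(-41, 6), rep(180, 6))
  bb <- torsions_to_backbone(t_aR)
  labels <- cyclicdesign:::rule_registry[["basin-letter"]](backbone_to_torsions(bb))
  expect_identical(paste(labels[-1], collapse = ""), "AAAAA")  # wrap phi(1) unconstrained
  # one positive-phi residue yields exactly one G there
  t_mix <- torsion_set(c(-63, -63, 60, -120, -75, -63),
                       c(-41, -41, 45, 130, 150, -41), rep(180, 6))
  bb2 <- torsions_to_backbone(t_mix)
  lab2 <- cyclicdesign:::rule_registry[["basin-letter"]](backbone_to_torsions(bb2))
  expect_identical(lab2[3], "G")
  expect_identical(sum(lab2[-1] == "G"), 1L)
  expect_error(make_rule_dataset(5, 6, rule = "nope"), "unknown rule")
})

test_that("rule labels recomputed from clean backbones match emitted sequences", {
  rd <- suppressWarnings(make_rule_dataset(20, 6, noise = 0.02, seed = 31))
  for (i in seq_along(rd$examples)) {
    lab <- cyclicdesign:::rule_registry[["basin-letter"]](
      backbone_to_torsions(rd$clean_backbones[[i]])
    )
    expect_identical(paste(lab, collapse = ""), rd$examples[[i]]$sequence)
  }
  # generation is deterministic under the seed
  rd2 <- suppressWarnings(make_rule_dataset(20, 6, noise = 0.02, seed = 31))
  expect_identical(rd$manifest, rd2$manifest)
  expect_identical(rd$examples[[3]]$backbone$N, rd2$examples[[3]]$backbone$N)
})

test_that("fixture PDBs round trip at format precision", {
  bb <- ensemble_fixture(6)$backbones[[1]]
  p <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(bb, p)
  rt <- read_backbone_pdb(p)
  for (a in c("N", "CA", "C", "O")) {
    expect_lt(max(abs(bb[[a]] - rt[[a]])), 5e-4)
  }
})
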