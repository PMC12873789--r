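test_that("P_Near limit cases are exact", {
  expect_equal(p_near(tibble::tibble(rmsd = 0, energy = -3)), 1.0)
  two <- tibble::tibble(rmsd = c(0, 1e9), energy = c(2, 2))
  expect_equal(p_near(two), 0.5)
  expect_error(p_near(tibble::tibble(rmsd = numeric(0), energy = numeric(0))),
               "non-empty")
})

test_that("the five-sample case matches direct summation of the formula", {
  ens <- tibble::tibble(
    rmsd = c(0.2, 0.5, 1.5, 3.0, 5.0),
    energy = c(-3, -2.5, -1, -3.5, 0)
  )
  cfg <- pnear_config(lambda = 1.5, kT = 0.62)
  direct <- sum(exp(-ens$rmsd^2 / 1.5^2) * exp(-ens$energy / 0.62)) /
    sum(exp(-ens$energy / 0.62))
  expect_equal(p_near(ens, cfg), direct, tolerance = 1e-12)
})

test_that("P_Near is invariant to energy offsets and sample order", {
  set.seed(8)
  for (k in 1:20) {
    ens <- tibble::tibble(rmsd = runif(12, 0, 6), energy = rnorm(12))
    v <- p_near(ens)
    expect_gte(v, 0)
    expect_lte(v, 1)
    shifted <- dplyr::mutate(ens, energy = energy + 137.5)
    expect_equal(p_near(shifted), v, tolerance = 1e-10)
    expect_equal(p_near(ens[sample(12), ]), v, tolerance = 1e-12)
  }
})

test_that("improving the lowest-energy sample's rmsd never lowers P_Near", {
  set.seed(9)
  for (k in 1:100) {
    ens <- tibble::tibble(rmsd = runif(10, 0.1, 6), energy = rnorm(10))
    i <- which.min(ens$energy)
    better <- ens
    better$rmsd[i] <- ens$rmsd[i] * runif(1)
    expect_gte(p_near(better) - p_near(ens), -1e-12)
  }
})

test_that("sequence recovery counts exact positional matches", {
  expect_equal(sequence_recovery("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(sequence_recovery("ACDEFG", "ACDEFA"), 5 / 6)
  expect_equal(sequence_recovery("AAAA", "WWWW"), 0.0)
  expect_error(sequence_recovery("AAA", "AAAA"), "differ")
})

test_that("uniqueness accounting is an exact multiset count", {
  u <- uniqueness_counts(rep("AAAA", 100))
  expect_identical(u$n_unique, 1L)
  expect_identical(u$table$count, 100L)
  distinct <- replicate(30, random_sequence(6))
  u2 <- uniqueness_counts(distinct)
  expect_identical(u2$n_unique, length(unique(distinct)))
  set.seed(10)
  multi <- sample(c("AA", "BB", "CC"), 50, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  u3 <- uniqueness_counts(multi)
  expect_identical(sum(u3$table$count), 50L)
  brute <- sort(table(multi), decreasing = TRUE)
  expect_identical(u3$table$count, as.integer(brute))
  # descending count, lexicographic within ties
  expect_false(is.unsorted(rev(u3$table$count)))
})

test_that("best-of-N prediction selection is the argmin with early ties", {
  ref <- ring_fixture(6)
  preds <- c(list(perturb_backbone(ref, 0.8, seed = 1)), list(ref),
             list(perturb_backbone(ref, 0.4, seed = 2)))
  got <- best_prediction_rmsd(preds, ref)
  expect_identical(got$index, 2L)
  expect_lt(got$rmsd, 1e-8)
  one <- best_prediction_rmsd(preds[1], ref)
  expect_equal(one$rmsd, backbone_rmsd(preds[[1]], ref))
  expect_error(best_prediction_rmsd(list(), ref), "no predictions")
  # known perturbation magnitudes order as expected against a direct scan
  mags <- c(0.6, 0.1, 0.9, 0.3, 0.45)
  ps <- lapply(seq_along(mags), function(i) perturb_backbone(ref, mags[i], seed = 40 + i))
  scan <- vapply(ps, backbone_rmsd, numeric(1), ref = ref)
  expect_identical(best_prediction_rmsd(ps, ref)$index, which.min(scan))
})

test_that("summary tables aggregate with midpoint medians", {
  rec <- tibble::tibble(
    length = c(6, 6, 6, 8, 8, 8, 8),
    sequence = c("A", "B", "A", "C", "D", "E", "F"),
    rmsd = c(1, 2, 3, 1, 2, 3, 4),
    plddt = c(80, 85, 90, NA, 70, 75, 80),
    native = c("A", "A", "A", "C", "C", "C", "C")
  )
  s <- summarize_designs(rec)
  expect_equal(s$median_rmsd[s$length == 6], 2)
  expect_equal(s$median_rmsd[s$length == 8], 2.5)  # even-n midpoint
  expect_identical(sum(s$n), nrow(rec))
  expect_equal(s$unique_fraction[s$length == 6], 2 / 3)
  expect_identical(s$n_missing_plddt[s$length == 8], 1L)
})
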