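test_that("RMSD filtering is inclusive and counts rejections", {
  rec <- tibble::tibble(
    backbone_id = c("a", "b", "c", "d"),
    length = c(6, 6, 10, 12),
    sequence = c("AAAAAA", "CCCCCC", "DDDDDDDDDD", "EEEEEEEEEEEE"),
    rmsd = c(0.35, 0.351, 0.5, 0.1)
  )
  flt <- suppressMessages(filter_designs(rec))
  expect_identical(flt$kept$backbone_id, c("a", "c"))  # boundary kept, 12-mer no threshold
  cnt <- flt$counts
  expect_identical(cnt$no_threshold[cnt$length == 12], 1L)
  expect_error(filter_designs(dplyr::mutate(rec, rmsd = c(0.1, NA, 0.2, 0.3))),
               "missing rmsd")
})

test_that("filtering a random table matches a brute-force scan", {
  set.seed(2)
  rec <- tibble::tibble(
    length = sample(c(6, 8, 10), 1000, replace = TRUE),
    sequence = "X",
    rmsd = runif(1000)
  )
  thr <- c("6" = 0.35, "8" = 0.35, "10" = 0.5)
  flt <- filter_designs(rec, thr)
  brute <- sum(mapply(function(l, r) r <= thr[[as.character(l)]],
                      rec$length, rec$rmsd))
  expect_identical(nrow(flt$kept), as.integer(brute))
})

test_that("greedy identity clustering handles the canonical cases", {
  expect_identical(cluster_sequences(c("AAAAAA", "AAAAAA", "WWWWWW")),
                   c(1L, 1L, 2L))
  expect_identical(cluster_sequences(c("AAAAAA", "AAAWWW")), c(1L, 1L))
  expect_identical(cluster_sequences(character(0)), integer(0))
})

test_that("clustering equals an independently coded greedy oracle", {
  set.seed(3)
  seqs <- replicate(200, random_sequence(8))
  got <- cluster_sequences(seqs, 0.3)
  # oracle: same ordering rule, nested-loop Hamming identity
  ord <- order(-nchar(seqs), seqs)
  assign <- integer(200)
  cents <- character(0)
  for (i in ord) {
    hit <- 0L
    for (ci in seq_along(cents)) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(cents[ci], "")[[1]]
      if (mean(a == b) >= 0.3) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      cents <- c(cents, seqs[i])
      hit <- length(cents)
    }
    assign[i] <- hit
  }
  expect_identical(got, assign)
})

test_that("identity uses the best ungapped offset for unequal lengths", {
  # "AAAA" against "WWAAAAWW": perfect 4-mer overlap, identity 4/8
  expect_equal(cyclicdesign:::pair_identity("AAAA", "WWAAAAWW"), 0.5)
  expect_equal(cyclicdesign:::pair_identity("AAAA", "WWWWWWWW"), 0)
})

test_that("splits never break clusters and are seeded", {
  clusters <- rep(1:20, each = 5)
  s1 <- make_splits(100, clusters, validation_fraction = 0.2, seed = 4)
  s2 <- make_splits(100, clusters, validation_fraction = 0.2, seed = 4)
  expect_identical(s1, s2)
  expect_identical(sort(c(s1$train, s1$validation)), 1:100)
  expect_length(intersect(unique(clusters[s1$train]),
                          unique(clusters[s1$validation])), 0)
  # fraction counts clusters: 10% of 100 singleton clusters = 10 records
  s3 <- make_splits(100, 1:100, validation_fraction = 0.1, seed = 1)
  expect_length(s3$validation, 10)
  expect_error(make_splits(10, rep(1L, 10)), "2 clusters")
})

test_that("perplexity is uniform-exact for a zeroed head and >= 1", {
  mp <- tiny_params()
  mp0 <- mp
  mp0$params$Wout[] <- 0
  mp0$params$bout[] <- 0
  ex <- lapply(closed_rings_fixture(8)[1:3], function(b) {
    list(backbone = b, sequence = random_sequence(8))
  })
  expect_equal(perplexity(mp0, ex), 20, tolerance = 1e-6)
  expect_gte(perplexity(mp, ex), 1)
})

test_that("checkpoint selection takes the perplexity argmin, earliest on ties", {
  fake <- function(ppl, epochs) {
    list(
      metrics = tibble::tibble(epoch = epochs, train_loss = 0,
                               val_perplexity = ppl),
      checkpoints = stats::setNames(
        lapply(epochs, function(e) structure(list(metadata = list(epoch = e)),
                                             class = "model_params")),
        epochs
      )
    )
  }
  sel <- select_checkpoint(fake(c(3.1, 2.4, 2.9), c(10, 20, 30)))
  expect_identical(sel$metadata$epoch, 20)
  sel <- select_checkpoint(fake(c(2.4, 2.4), c(10, 20)))
  expect_identical(sel$metadata$epoch, 10)
  expect_error(select_checkpoint(list(checkpoints = list())), "no checkpoints")
})

test_that("training is bit-deterministic given the seed", {
  bbs <- closed_rings_fixture(8)[1:6]
  seqs <- withr::with_seed(5, replicate(6, random_sequence(8)))
  cfg <- model_config(hidden_dim = 8, enc_layers = 1, dec_layers = 1,
                      n_rbf = 3, d_max = 4)
  tc <- train_config(epochs = 3, eval_every = 3, seed = 9)
  ds <- make_dataset(bbs, seqs, tc)
  r1 <- finetune(init_params(cfg, seed = 1), ds, tc)
  r2 <- finetune(init_params(cfg, seed = 1), ds, tc)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$final$params, r2$final$params)
})

test_that("fine-tuning a pretrained checkpoint lowers validation perplexity", {
  rd <- suppressWarnings(make_rule_dataset(40, 6, noise = 0.02, seed = 17))
  clusters <- cluster_sequences(rd$manifest$sequence)
  ds <- structure(list(examples = rd$examples, clusters = clusters,
                       train = 1:30, validation = 31:40),
                  class = "design_dataset")
  cfg <- model_config(hidden_dim = 32, enc_layers = 1, dec_layers = 1)
  tc <- train_config(epochs = 8, eval_every = 8, cluster_sampling = FALSE,
                     backbone_noise = 0.02, seed = 21)
  # "pretrained" toy checkpoint: a short run on the first half
  pre <- finetune(init_params(cfg, seed = 2),
                  structure(list(examples = rd$examples, clusters = clusters,
                                 train = 1:15, validation = 31:40),
                            class = "design_dataset"),
                  train_config(epochs = 2, eval_every = 2,
                               cluster_sampling = FALSE, seed = 5))$final
  before <- perplexity(pre, ds$examples[ds$validation])
  run <- finetune(pre, ds, tc)
  after <- perplexity(run$final, ds$examples[ds$validation])
  expect_lt(after, before)
})
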