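# Dataset assembly, greedy sequence clustering, cluster-aware fine-tuning
# with perplexity tracking, and lowest-perplexity checkpoint selection.

#' Filter design records by length-dependent RMSD thresholds
#'
#' The dataset-creation rule: a designed sequence enters the fine-tuning
#' set iff its predicted-structure backbone RMSD to the input backbone is
#' at or below the length threshold (inclusive): 0.35 Angstrom for 6- and
#' 8-mers, 0.5 for 10-mers by default. Records whose length has no
#' threshold are rejected and counted.
#'
#' @param records a tibble/data.frame with at least `length` and `rmsd`
#'   columns (one row per design).
#' @param thresholds named numeric vector mapping length to Angstrom
#'   cutoff.
#' @return a list: `kept` (surviving rows, same columns), `counts`
#'   (tibble: length, n, kept, dropped, no_threshold).
#' @export
filter_designs <- function(records,
                           thresholds = c("6" = 0.35, "8" = 0.35, "10" = 0.5)) {
  records <- tibble::as_tibble(records)
  if (!all(c("length", "rmsd") %in% names(records))) {
    abort_invalid("records need `length` and `rmsd` columns")
  }
  if (anyNA(records$rmsd)) {
    abort_invalid(sprintf(
      "missing rmsd for record(s): %s",
      paste(utils::head(which(is.na(records$rmsd)), 5), collapse = ", ")
    ))
  }
  thr <- thresholds[as.character(records$length)]
  known <- !is.na(thr)
  keep <- known & records$rmsd <= thr
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    message(sprintf("%d record(s) of lengths without a threshold rejected", n_unknown))
  }
  counts <- records |>
    dplyr::mutate(.keep_flag = keep, .known = known) |>
    dplyr::group_by(length) |>
    dplyr::summarise(
      n = dplyr::n(), kept = sum(.keep_flag),
      dropped = sum(.known & !.keep_flag), no_threshold = sum(!.known),
      .groups = "drop"
    )
  list(kept = records[keep, , drop = FALSE], counts = counts)
}

# ungapped pairwise identity: exact matches over the longer length,
# maximised over offsets (Hamming when lengths agree)
pair_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  la <- length(va)
  lb <- length(vb)
  if (la == lb) return(sum(va == vb) / la)
  if (la < lb) {
    tmp <- va; va <- vb; vb <- tmp
    tmp <- la; la <- lb; lb <- tmp
  }
  best <- 0L
  for (off in 0:(la - lb)) {
    best <- max(best, sum(va[off + seq_len(lb)] == vb))
  }
  best / la
}

#' Greedy sequence identity clustering
#'
#' Redundancy-reduction clustering: sequences are visited by descending
#' length, ties broken lexicographically; each joins the first existing
#' cluster whose centroid it matches at or above the identity threshold,
#' otherwise it founds a new cluster with itself as centroid. Identity is
#' ungapped: exact matches over the longer length, maximised over offsets
#' (plain Hamming fraction for equal lengths).
#'
#' @param seqs character vector of sequences.
#' @param identity_threshold fraction in (0, 1] (default 0.3, the usual
#'   redundancy threshold for fine-tuning sets).
#' @return integer cluster id per input sequence (1-based, in input
#'   order); empty input gives an empty vector.
#' @export
cluster_sequences <- function(seqs, identity_threshold = 0.3) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort_invalid("identity_threshold must be in (0, 1]")
  }
  ord <- order(-nchar(seqs), seqs)
  assign <- integer(n)
  centroids <- character(0)
  for (i in ord) {
    placed <- FALSE
    for (cid in seq_along(centroids)) {
      if (pair_identity(seqs[i], centroids[cid]) >= identity_threshold) {
        assign[i] <- cid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, seqs[i])
      assign[i] <- length(centroids)
    }
  }
  assign
}

#' Cluster-granular train/validation split
#'
#' Whole clusters go to one side only, so no validation sequence shares a
#' cluster with any training sequence. Deterministic given the seed.
#'
#' @param n number of records.
#' @param clusters integer cluster id per record (from
#'   [cluster_sequences()]).
#' @param validation_fraction fraction of clusters held out (default 0.1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
make_splits <- function(n, clusters, validation_fraction = 0.1, seed = 1) {
  if (length(clusters) != n) abort_invalid("clusters must have one id per record")
  ids <- unique(clusters)
  if (length(ids) < 2) abort_invalid("need at least 2 clusters to split")
  n_val <- max(1L, round(validation_fraction * length(ids)))
  val_ids <- withr::with_seed(seed, sample(ids, n_val))
  list(
    train = which(!(clusters %in% val_ids)),
    validation = which(clusters %in% val_ids)
  )
}

#' Training configuration
#'
#' @param epochs passes over the (cluster-sampled) training set
#'   (default 200, the fine-tuning recipe's length).
#' @param batch_size examples per optimiser step.
#' @param lr peak Adam learning rate.
#' @param warmup_steps inverse-sqrt warmup horizon (optimiser steps).
#' @param label_smoothing cross-entropy smoothing weight (default 0.1).
#' @param backbone_noise Gaussian coordinate noise std in Angstrom applied
#'   to every training example each visit (default 0.1).
#' @param grad_clip global gradient-norm clip (default 1).
#' @param validation_fraction cluster fraction held out (default 0.1).
#' @param identity_threshold clustering identity (default 0.3).
#' @param cluster_sampling sample one member per cluster per epoch
#'   (default TRUE, the redundancy-aware recipe); FALSE visits every
#'   training record each epoch.
#' @param eval_every epochs between validation-perplexity evaluations and
#'   checkpoints (default 10).
#' @param seed master seed; per-epoch RNG streams derive from it.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 8, lr = 1e-3,
                         warmup_steps = 100, label_smoothing = 0.1,
                         backbone_noise = 0.1, grad_clip = 1,
                         validation_fraction = 0.1,
                         identity_threshold = 0.3,
                         cluster_sampling = TRUE,
                         eval_every = 10, seed = 1) {
  if (epochs < 1) abort_invalid("epochs must be >= 1")
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort_invalid("identity_threshold must be in (0, 1]")
  }
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, warmup_steps = as.integer(warmup_steps),
      label_smoothing = label_smoothing, backbone_noise = backbone_noise,
      grad_clip = grad_clip, validation_fraction = validation_fraction,
      identity_threshold = identity_threshold,
      cluster_sampling = isTRUE(cluster_sampling),
      eval_every = as.integer(eval_every), seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Assemble a training dataset
#'
#' Clusters the sequences, splits at cluster granularity and packages
#' everything [finetune()] needs.
#'
#' @param backbones list of [backbone()]s.
#' @param sequences character vector, one sequence per backbone.
#' @param config a [train_config()].
#' @return a list of class `design_dataset`: `examples` (list of
#'   `list(backbone, sequence)`), `clusters`, `train`, `validation`.
#' @export
make_dataset <- function(backbones, sequences, config = train_config()) {
  if (length(backbones) != length(sequences)) {
    abort_invalid("one sequence per backbone required")
  }
  if (length(backbones) == 0) abort_invalid("dataset is empty")
  clusters <- cluster_sequences(sequences, config$identity_threshold)
  split <- make_splits(length(backbones), clusters,
                       config$validation_fraction, config$seed)
  structure(
    list(
      examples = Map(function(b, s) list(backbone = b, sequence = s),
                     backbones, sequences),
      clusters = clusters, train = split$train, validation = split$validation
    ),
    class = "design_dataset"
  )
}

# Adam update; state carries first/second moments and the step counter.
adam_step <- function(params, grads, state, lr) {
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# smoothed cross-entropy loss and dlogits for one teacher-forced example
ce_loss_grad <- function(logits, seq_int, label_smoothing) {
  L <- nrow(logits)
  lse <- logsumexp_rows(logits)
  logp <- logits - lse
  tgt <- matrix(label_smoothing / 20, L, 20)
  tgt[cbind(seq_len(L), seq_int)] <-
    tgt[cbind(seq_len(L), seq_int)] + (1 - label_smoothing)
  loss <- -sum(tgt * logp) / L
  dlogits <- (softmax_rows(logits) - tgt) / L
  list(loss = loss, dlogits = dlogits)
}

#' Teacher-forced dataset perplexity
#'
#' exp of the mean per-residue negative log-likelihood over every residue
#' of the dataset examples, scored with the fixed left-to-right decoding
#' order and no label smoothing.
#'
#' @param params a `model_params`.
#' @param examples list of `list(backbone, sequence)`.
#' @return perplexity (>= 1; exactly 20 for a uniform model).
#' @export
perplexity <- function(params, examples) {
  tot <- 0
  n <- 0
  for (ex in examples) {
    d <- score_sequence(ex$backbone, ex$sequence, params)
    tot <- tot + sum(d$nll)
    n <- n + length(d$nll)
  }
  exp(tot / n)
}

#' Teacher-forced sequence recovery
#'
#' Fraction of positions at which the model's argmax letter (conditioned
#' on the true letters before each position, left-to-right) equals the
#' true letter, over all dataset examples.
#'
#' @inheritParams perplexity
#' @return fraction in [0, 1].
#' @export
teacher_forced_recovery <- function(params, examples) {
  hit <- 0
  n <- 0
  for (ex in examples) {
    bb <- ex$backbone
    seq_int <- seq_to_int(ex$sequence)
    feat <- featurize(bb, params$config)
    mask <- order_mask(seq_len(feat$L), feat$i_idx, feat$j_idx)
    out <- model_forward(params, feat, seq_int, mask)
    hit <- hit + sum(max.col(out$logits) == seq_int)
    n <- n + feat$L
  }
  hit / n
}

#' Fine-tune (or train) the model on a design dataset
#'
#' Each epoch draws one member per training cluster (uniformly, with an
#' epoch-specific RNG stream derived from the master seed), perturbs its
#' backbone coordinates with Gaussian noise, scores it teacher-forced
#' under a random decoding order, and optimises smoothed cross-entropy
#' with Adam (inverse-sqrt warmup schedule, global gradient clipping).
#' Validation perplexity is evaluated and a checkpoint stored every
#' `eval_every` epochs and at the final epoch.
#'
#' @param init a `model_params` starting point (pretrained or
#'   [init_params()]).
#' @param dataset a [make_dataset()] result.
#' @param config a [train_config()].
#' @return a list of class `finetune_run`: `metrics` (tibble: epoch,
#'   train_loss, val_perplexity), `checkpoints` (named list of
#'   `model_params` keyed by epoch), `final` (last-epoch params).
#' @export
finetune <- function(init, dataset, config = train_config()) {
  params <- init$params
  cfg_model <- init$config
  state <- list(
    t = 0L,
    m = lapply(params, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))),
    v = lapply(params, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  )
  train_idx <- dataset$train
  val_ex <- dataset$examples[dataset$validation]
  clusters_train <- dataset$clusters[train_idx]
  metrics <- tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                            val_perplexity = numeric(0))
  checkpoints <- list()
  mp <- init
  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- withr::with_seed(config$seed + epoch, {
      visit <- if (config$cluster_sampling) {
        vapply(split(seq_along(train_idx), clusters_train),
               function(members) members[sample.int(length(members), 1)],
               integer(1))
      } else {
        seq_along(train_idx)
      }
      visit <- sample(visit)
      losses <- numeric(0)
      batch_grads <- NULL
      batch_n <- 0L
      for (vi in visit) {
        ex <- dataset$examples[[train_idx[vi]]]
        bb <- ex$backbone
        if (config$backbone_noise > 0) {
          for (a in BACKBONE_ATOMS) {
            bb[[a]] <- bb[[a]] + matrix(stats::rnorm(length(bb[[a]]), 0, config$backbone_noise),
                                        nrow(bb[[a]]), 3)
          }
        }
        seq_int <- seq_to_int(ex$sequence)
        feat <- featurize(bb, cfg_model)
        ord <- sample.int(feat$L)
        mask <- order_mask(ord, feat$i_idx, feat$j_idx)
        drop_masks <- NULL
        if (cfg_model$dropout > 0) {
          drop_masks <- list()
          keep <- 1 - cfg_model$dropout
          for (l in seq_len(cfg_model$enc_layers)) {
            drop_masks[[paste0("enc", l)]] <-
              matrix(stats::rbinom(feat$L * feat$k * cfg_model$hidden_dim, 1, keep) / keep,
                     feat$L * feat$k, cfg_model$hidden_dim)
          }
          for (l in seq_len(cfg_model$dec_layers)) {
            drop_masks[[paste0("dec", l)]] <-
              matrix(stats::rbinom(feat$L * feat$k * cfg_model$hidden_dim, 1, keep) / keep,
                     feat$L * feat$k, cfg_model$hidden_dim)
          }
        }
        mp$params <- params
        out <- model_forward(mp, feat, seq_int, mask, want_cache = TRUE,
                             drop_masks = drop_masks)
        lg <- ce_loss_grad(out$logits, seq_int, config$label_smoothing)
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        losses <- c(losses, lg$loss)
        g <- model_backward(mp, feat, out$cache, lg$dlogits)
        batch_grads <- if (is.null(batch_grads)) g else Map(`+`, batch_grads, g)
        batch_n <- batch_n + 1L
        if (batch_n == config$batch_size || vi == visit[length(visit)]) {
          g_avg <- lapply(batch_grads, function(x) x / batch_n)
          gnorm <- sqrt(sum(vapply(g_avg, function(x) sum(x^2), numeric(1))))
          if (gnorm > config$grad_clip) {
            g_avg <- lapply(g_avg, function(x) x * config$grad_clip / gnorm)
          }
          step <- state$t + 1L
          lr_t <- config$lr * min(step / config$warmup_steps,
                                  sqrt(config$warmup_steps / step))
          upd <- adam_step(params, g_avg, state, lr_t)
          params <- upd$params
          state <- upd$state
          batch_grads <- NULL
          batch_n <- 0L
        }
      }
      mean(losses)
    })
    val_ppl <- NA_real_
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      mp$params <- params
      mp$metadata <- list(epoch = epoch)
      if (length(val_ex)) {
        val_ppl <- perplexity(mp, val_ex)
        mp$metadata$perplexity <- val_ppl
      }
      checkpoints[[as.character(epoch)]] <- mp
    }
    metrics <- dplyr::bind_rows(metrics, tibble::tibble(
      epoch = epoch, train_loss = epoch_loss, val_perplexity = val_ppl
    ))
  }
  mp$params <- params
  structure(list(metrics = metrics, checkpoints = checkpoints, final = mp),
            class = "finetune_run")
}

#' Select the lowest-perplexity checkpoint
#'
#' The fine-tuning recipe's model-selection rule: among checkpointed
#' epochs, return the one with the lowest validation perplexity; ties go
#' to the earliest epoch.
#'
#' @param run a [finetune()] result (or a list with `metrics` and
#'   `checkpoints` shaped the same way).
#' @return the selected `model_params`.
#' @export
select_checkpoint <- function(run) {
  cps <- run$checkpoints
  if (!length(cps)) abort_invalid("no checkpoints recorded")
  epochs <- as.integer(names(cps))
  ppl <- run$metrics$val_perplexity[match(epochs, run$metrics$epoch)]
  if (all(is.na(ppl))) abort_invalid("no validation perplexity recorded")
  ord <- order(ppl, epochs)
  cps[[ord[1]]]
}
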