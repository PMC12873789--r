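# The end-to-end pipeline: sample backbones -> design sequences ->
# fold (external hook or perturbation stand-in) -> filter -> optional
# fine-tuning -> evaluation, with a single master seed fanned out to
# per-stage seeds and every artifact written to the output directory.

pipeline_defaults <- function() {
  list(
    lengths = c(6L),
    n_per_length = 20L,
    seed = 1L,
    out_dir = "cyclicdesign_run",
    sampler = list(rama_cutoff = 2, min_hbonds = NULL, attempt_factor = 50),
    design = list(n = 5L, temperature = 0.1, cyclic = TRUE,
                  hidden_dim = 64L, enc_layers = 2L, dec_layers = 2L,
                  weights = "random"),
    folding = list(method = "perturb", sigma = 0.3, n_predictions = 5L,
                   command = NULL),
    filter = list(thresholds = c("6" = 0.35, "8" = 0.35, "10" = 0.5)),
    train = list(enabled = FALSE, epochs = 30L, eval_every = 10L,
                 cluster_sampling = TRUE),
    log_level = "info"
  )
}

check_keys <- function(given, template, path = "") {
  for (nm in names(given)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(template)) {
      abort_invalid(sprintf("unknown configuration key: %s", full))
    }
    if (is.list(given[[nm]]) && is.list(template[[nm]]) &&
        !is.null(names(template[[nm]]))) {
      check_keys(given[[nm]], template[[nm]], full)
    }
  }
}

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]; any subset of keys may be
#' overridden, unknown keys are rejected by name. Round-trips losslessly
#' through its JSON file representation.
#'
#' @param ... overrides of the defaults (see `pipeline_defaults`):
#'   `lengths`, `n_per_length`, `seed`, `out_dir`, and the nested
#'   `sampler`, `design`, `folding`, `filter`, `train` blocks.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  given <- list(...)
  defaults <- pipeline_defaults()
  check_keys(given, defaults)
  cfg <- utils::modifyList(defaults, given)
  # canonical types so file round trips compare identical
  cfg$lengths <- as.integer(cfg$lengths)
  cfg$n_per_length <- as.integer(cfg$n_per_length)
  cfg$seed <- as.integer(cfg$seed)
  cfg$sampler$rama_cutoff <- as.numeric(cfg$sampler$rama_cutoff)
  if (!("min_hbonds" %in% names(cfg$sampler))) cfg$sampler["min_hbonds"] <- list(NULL)
  if (!is.null(cfg$sampler$min_hbonds)) cfg$sampler$min_hbonds <- as.integer(cfg$sampler$min_hbonds)
  cfg$sampler <- cfg$sampler[c("rama_cutoff", "min_hbonds", "attempt_factor")]
  cfg$sampler$attempt_factor <- as.numeric(cfg$sampler$attempt_factor)
  for (f in c("n", "hidden_dim", "enc_layers", "dec_layers")) {
    cfg$design[[f]] <- as.integer(cfg$design[[f]])
  }
  cfg$design$temperature <- as.numeric(cfg$design$temperature)
  cfg$folding$sigma <- as.numeric(cfg$folding$sigma)
  cfg$folding$n_predictions <- as.integer(cfg$folding$n_predictions)
  if (!("command" %in% names(cfg$folding))) cfg$folding["command"] <- list(NULL)
  thr <- unlist(cfg$filter$thresholds)
  if (is.null(names(thr)) || any(!nzchar(names(thr)))) {
    abort_invalid("filter thresholds must be named by length")
  }
  cfg$filter$thresholds <- stats::setNames(as.numeric(thr), names(thr))
  cfg$train$enabled <- isTRUE(cfg$train$enabled)
  cfg$train$epochs <- as.integer(cfg$train$epochs)
  cfg$train$eval_every <- as.integer(cfg$train$eval_every)
  cfg$train$cluster_sampling <- isTRUE(cfg$train$cluster_sampling)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$filter$thresholds)) {
    raw$filter$thresholds <- unlist(raw$filter$thresholds)
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$filter$thresholds <- as.list(out$filter$thresholds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# stage seeds derive from the master seed by fixed offsets (documented;
# kept well below 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(sample = 101L, design = 202L, fold = 303L, train = 404L)
  (seed %% 100000000L) * 10L + offs[[stage]]
}

plog <- function(level, cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full design pipeline
#'
#' sample -> design -> fold -> filter -> (optional fine-tune) ->
#' evaluate. The folding stage is pluggable: `method = "perturb"` uses
#' the Gaussian perturbation stand-in (each design's "predicted"
#' structures are noisy copies of its backbone; the lowest-RMSD one is
#' kept), while `method = "command"` invokes a user command template
#' containing `{pdb}`, `{seq}` and `{out}` placeholders that must produce
#' predicted-structure PDB files in `{out}`. Every stage writes its
#' outputs, and reruns with the same config and seed reproduce all
#' non-external outputs byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list: `records` (all design records),
#'   `kept`, `summary`, `out_dir`, plus `selected_model` when training
#'   ran.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "backbones"), showWarnings = FALSE)
  write_pipeline_config(config, file.path(out, "config.json"))
  seed <- as.integer(config$seed)

  # model parameters for design
  dcfg <- config$design
  mcfg <- model_config(hidden_dim = dcfg$hidden_dim,
                       enc_layers = dcfg$enc_layers,
                       dec_layers = dcfg$dec_layers, cyclic = dcfg$cyclic)
  params <- if (identical(dcfg$weights, "random")) {
    init_params(mcfg, seed = stage_seed(seed, "design"))
  } else {
    load_model(dcfg$weights)
  }

  backbone_index <- list()
  records <- NULL
  all_stats <- NULL
  for (L in config$lengths) {
    plog("info", config, "sampling %d backbones of length %d", config$n_per_length, L)
    scfg <- sampler_config(
      L, n_target = config$n_per_length,
      rama_cutoff = config$sampler$rama_cutoff,
      min_hbonds = config$sampler$min_hbonds,
      attempt_cap = config$sampler$attempt_factor * config$n_per_length,
      seed = stage_seed(seed, "sample") + L
    )
    ens <- generate_ensemble(scfg)
    all_stats <- dplyr::bind_rows(all_stats,
                                  dplyr::mutate(ens$stats, length = L))
    plog("info", config, "designing sequences (best of %d)", dcfg$n)
    for (bi in seq_along(ens$backbones)) {
      bb <- ens$backbones[[bi]]
      write_backbone_pdb(bb, file.path(out, "backbones", paste0(bb$id, ".pdb")))
      backbone_index[[bb$id]] <- bb
      des <- design(bb, params, n = dcfg$n, temperature = dcfg$temperature,
                    seed = stage_seed(seed, "design") + 131L * bi + L)
      # folding stage
      fold_seed <- stage_seed(seed, "fold") + 131L * bi + L
      if (identical(config$folding$method, "perturb")) {
        preds <- lapply(seq_len(config$folding$n_predictions), function(p) {
          perturb_backbone(bb, config$folding$sigma, seed = fold_seed + p)
        })
      } else {
        preds <- fold_with_command(config$folding$command, bb, des$best$sequence, out)
      }
      best <- best_prediction_rmsd(preds, bb)
      records <- dplyr::bind_rows(records, tibble::tibble(
        backbone_id = bb$id, length = L, sequence = des$best$sequence,
        score = des$best$global_score, rmsd = best$rmsd,
        source = "in_silico"
      ))
    }
  }
  write_tsv_versioned(records, file.path(out, "designs.tsv"))
  write_tsv_versioned(all_stats, file.path(out, "sampler_stats.tsv"))

  flt <- filter_designs(records, config$filter$thresholds)
  write_tsv_versioned(flt$kept, file.path(out, "designs_kept.tsv"))
  write_tsv_versioned(flt$counts, file.path(out, "filter_counts.tsv"))

  selected <- NULL
  if (isTRUE(config$train$enabled) && nrow(flt$kept) > 0) {
    plog("info", config, "fine-tuning on %d kept designs", nrow(flt$kept))
    tc <- train_config(epochs = config$train$epochs,
                       eval_every = config$train$eval_every,
                       cluster_sampling = config$train$cluster_sampling,
                       seed = stage_seed(seed, "train"))
    ds <- make_dataset(backbone_index[flt$kept$backbone_id],
                       flt$kept$sequence, tc)
    run <- finetune(params, ds, tc)
    write_tsv_versioned(run$metrics, file.path(out, "metrics.tsv"))
    selected <- select_checkpoint(run)
    save_model(selected, file.path(out, "selected.ckpt"))
  }

  summary <- summarize_designs(records)
  write_tsv_versioned(summary, file.path(out, "summary.tsv"))
  plog("info", config, "pipeline complete: %s", out)
  invisible(list(records = records, kept = flt$kept, summary = summary,
                 out_dir = out, selected_model = selected,
                 sampler_stats = all_stats))
}

# external folding hook: run a user command template per design
fold_with_command <- function(template, bb, seq, out) {
  if (is.null(template)) abort_invalid("folding method 'command' needs a command template")
  pdb <- tempfile(fileext = ".pdb")
  write_backbone_pdb(bb, pdb)
  pred_dir <- tempfile("fold_out_")
  dir.create(pred_dir)
  cmd <- gsub("{pdb}", pdb, gsub("{seq}", seq, gsub("{out}", pred_dir, template,
              fixed = TRUE), fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0) stop(sprintf("folding command failed (exit %d): %s", status, cmd))
  files <- list.files(pred_dir, pattern = "\\.pdb$", full.names = TRUE)
  if (!length(files)) stop("folding command produced no PDB files")
  lapply(sort(files), read_backbone_pdb)
}
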