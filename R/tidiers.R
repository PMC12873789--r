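# Tidy/glance methods and plotting for the package's result objects, so
# results drop straight into dplyr/ggplot2 workflows.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design result
#'
#' One row per residue: position, letter, negative log-likelihood.
#'
#' @param x a `design_result` from [score_sequence()] or [decode_sample()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.design_result <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$nll),
    letter = strsplit(x$sequence, "")[[1]],
    nll = x$nll
  )
}

#' @rdname tidy.design_result
#' @export
glance.design_result <- function(x, ...) {
  tibble::tibble(
    sequence = x$sequence, global_score = x$global_score,
    perplexity = exp(x$global_score), temperature = x$temperature
  )
}

#' Tidy a backbone ensemble
#'
#' One row per accepted conformation with its closure residual and
#' hydrogen-bond count.
#'
#' @param x a `backbone_ensemble` from [generate_ensemble()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.backbone_ensemble <- function(x, ...) {
  tibble::tibble(
    id = vapply(x$backbones, function(b) b$id, character(1)),
    length = vapply(x$backbones, length, integer(1)),
    bond_dev = vapply(x$backbones, function(b) closure_residual(b)$bond_dev, numeric(1)),
    hbonds = vapply(x$backbones, hbond_count, integer(1))
  )
}

#' @rdname tidy.backbone_ensemble
#' @export
glance.backbone_ensemble <- function(x, ...) x$stats

#' Glance at a fine-tuning run
#'
#' @param x a `finetune_run` from [finetune()].
#' @param ... unused.
#' @return a one-row tibble: epochs run, final train loss, best
#'   validation perplexity and its epoch.
#' @export
glance.finetune_run <- function(x, ...) {
  m <- x$metrics
  evald <- m[!is.na(m$val_perplexity), ]
  best <- if (nrow(evald)) evald[which.min(evald$val_perplexity), ] else NULL
  tibble::tibble(
    epochs = max(m$epoch), final_train_loss = m$train_loss[nrow(m)],
    best_val_perplexity = if (is.null(best)) NA_real_ else best$val_perplexity,
    best_epoch = if (is.null(best)) NA_integer_ else best$epoch
  )
}

#' @rdname glance.finetune_run
#' @export
tidy.finetune_run <- function(x, ...) x$metrics

#' Plot a fine-tuning run
#'
#' Training loss and validation perplexity against epoch.
#'
#' @param object a `finetune_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_training <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  m <- object$metrics
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = m$epoch, value = m$train_loss, metric = "train loss"),
    tibble::tibble(epoch = m$epoch, value = m$val_perplexity, metric = "validation perplexity")
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
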