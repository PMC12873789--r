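# Post-design statistics: the P_Near folding-funnel metric, sequence
# recovery, uniqueness accounting, best-of-N selection and aggregate
# summary tables.

#' P_Near configuration
#'
#' `lambda` sets the breadth (Angstrom) of the near-native well and `kT`
#' the Boltzmann temperature in the energy units of the ensemble. The
#' defaults (1.5 Angstrom, 0.62) are the values commonly used for cyclic
#' peptide folding-funnel analysis in Rosetta-style workflows; both must
#' be stated explicitly in configuration files to avoid silent unit
#' mismatches.
#'
#' @param lambda near-native well breadth in Angstrom (> 0).
#' @param kT Boltzmann factor in energy units (> 0).
#' @return an object of class `pnear_config`.
#' @export
pnear_config <- function(lambda = 1.5, kT = 0.62) {
  if (lambda <= 0 || kT <= 0) abort_invalid("lambda and kT must be positive")
  structure(list(lambda = lambda, kT = kT), class = "pnear_config")
}

#' P_Near folding-funnel statistic
#'
#' For an ensemble of conformational samples with RMSD-to-native r_i and
#' energy E_i,
#' \deqn{P_{Near} = \frac{\sum_i e^{-r_i^2/\lambda^2} e^{-E_i/k_BT}}
#'                       {\sum_i e^{-E_i/k_BT}}}
#' computed with the log-sum-exp trick. Near 1 when low-energy samples
#' cluster at the native structure; near 0 when the landscape favours
#' non-native states. Invariant to energy offsets and sample order.
#'
#' @param samples a data.frame/tibble with columns `rmsd` and `energy`.
#' @param config a [pnear_config()].
#' @return a value in [0, 1].
#' @export
p_near <- function(samples, config = pnear_config()) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("rmsd", "energy") %in% names(samples)) || nrow(samples) == 0) {
    abort_invalid("need a non-empty table with `rmsd` and `energy` columns")
  }
  if (!all(is.finite(samples$rmsd)) || !all(is.finite(samples$energy))) {
    abort_invalid("non-finite rmsd or energy")
  }
  a <- -samples$rmsd^2 / config$lambda^2 - samples$energy / config$kT
  b <- -samples$energy / config$kT
  m <- max(b)
  exp((m + log(sum(exp(a - m)))) - (m + log(sum(exp(b - m)))))
}

#' Positional sequence recovery
#'
#' Exact positional matches divided by length.
#'
#' @param native,designed equal-length sequences.
#' @return fraction in [0, 1].
#' @export
sequence_recovery <- function(native, designed) {
  a <- strsplit(toupper(native), "")[[1]]
  b <- strsplit(toupper(designed), "")[[1]]
  if (length(a) != length(b)) abort_invalid("sequence lengths differ")
  mean(a == b)
}

#' Sequence uniqueness accounting
#'
#' Exact multiset accounting of a design batch: how many distinct
#' sequences, and how often each occurs (the repetition profile the
#' design methods are compared on).
#'
#' @param seqs character vector of sequences.
#' @return a list: `n_unique`, `table` (tibble `sequence`, `count`,
#'   sorted by descending count then lexicographically).
#' @export
uniqueness_counts <- function(seqs) {
  if (length(seqs) == 0) {
    return(list(n_unique = 0L,
                table = tibble::tibble(sequence = character(0), count = integer(0))))
  }
  tab <- tibble::as_tibble(as.data.frame(table(sequence = seqs),
                                         stringsAsFactors = FALSE))
  names(tab) <- c("sequence", "count")
  tab$count <- as.integer(tab$count)
  tab <- dplyr::arrange(tab, dplyr::desc(count), sequence)
  list(n_unique = nrow(tab), table = tab)
}

#' Best prediction by backbone RMSD
#'
#' The post-folding selection rule: among several predicted structures
#' for one design, keep the one with the lowest backbone RMSD to the
#' reference; ties go to the earliest.
#'
#' @param predictions list of [backbone()]s.
#' @param reference a [backbone()] of matching length.
#' @param atoms atom subset for [backbone_rmsd()].
#' @return a list: `rmsd` (minimum), `index`, `all` (numeric vector).
#' @export
best_prediction_rmsd <- function(predictions, reference, atoms = BACKBONE_ATOMS) {
  if (length(predictions) == 0) abort_invalid("no predictions given")
  r <- vapply(predictions, backbone_rmsd, numeric(1), ref = reference, atoms = atoms)
  list(rmsd = min(r), index = which.min(r), all = r)
}

#' Summarise a design-record table
#'
#' Per-length aggregates of the pipeline's record table: median/mean
#' RMSD, median/mean pLDDT where present, sequence recovery statistics
#' where a native sequence is given, and the unique-sequence fraction.
#' Medians use the midpoint convention (average of the two central order
#' statistics for even n).
#'
#' @param records tibble with columns `length`, `sequence`, `rmsd`, and
#'   optionally `plddt`, `native`.
#' @return a tibble, one row per length.
#' @export
summarize_designs <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(length = integer(0)))
  }
  has_plddt <- "plddt" %in% names(records)
  has_native <- "native" %in% names(records)
  records |>
    dplyr::group_by(length) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_rmsd = stats::median(rmsd),
      mean_rmsd = mean(rmsd),
      median_plddt = if (has_plddt) stats::median(plddt, na.rm = TRUE) else NA_real_,
      mean_plddt = if (has_plddt) mean(plddt, na.rm = TRUE) else NA_real_,
      n_missing_plddt = if (has_plddt) sum(is.na(plddt)) else dplyr::n(),
      mean_recovery = if (has_native) {
        mean(mapply(sequence_recovery, native, sequence))
      } else NA_real_,
      unique_fraction = dplyr::n_distinct(sequence) / dplyr::n(),
      .groups = "drop"
    )
}
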