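# PDB and FASTA readers/writers. Fixed-width wwPDB v3.3 ATOM records,
# single chain, backbone atoms only; head-to-tail cyclisation is noted in
# a REMARK line rather than CONECT records so downstream parsers stay
# happy.

PDB_CYCLIC_REMARK <- "REMARK 999 HEAD-TO-TAIL CYCLIC PEPTIDE"

#' Write a backbone to PDB
#'
#' Standard ATOM records (chain A, residues 1..L, poly-alanine residue
#' names, occupancy 1.00, B 0.00, element column filled). The cyclic flag
#' is recorded as a REMARK. Output is byte-deterministic: no timestamps.
#'
#' @param bb a [backbone()].
#' @param path output file path.
#' @export
write_backbone_pdb <- function(bb, path) {
  L <- length(bb)
  lines <- character(0)
  if (bb$cyclic) lines <- PDB_CYCLIC_REMARK
  serial <- 0L
  atom_names <- c(N = " N  ", CA = " CA ", C = " C  ", O = " O  ")
  elements <- c(N = "N", CA = "C", C = "C", O = "O")
  for (i in seq_len(L)) {
    for (a in BACKBONE_ATOMS) {
      serial <- serial + 1L
      xyz <- bb[[a]][i, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom_names[[a]], "ALA", "A", i, xyz[1], xyz[2], xyz[3],
        1, 0, elements[[a]]
      ))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a backbone from PDB
#'
#' Parses ATOM records for the N, CA, C and O atoms of a single chain.
#' Residues are ordered by residue number; alternate locations resolve to
#' the highest occupancy (first on ties); insertion codes are rejected. A
#' missing O on the final residue of a linear chain is rebuilt from ideal
#' geometry with a warning. The cyclic flag is restored from the REMARK
#' written by [write_backbone_pdb()] unless overridden.
#'
#' @param path PDB file.
#' @param chain chain identifier to read; required when several chains
#'   are present.
#' @param cyclic logical override; `NULL` (default) uses the REMARK.
#' @return a [backbone()].
#' @export
read_backbone_pdb <- function(path, chain = NULL, cyclic = NULL) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_cyclic <- any(startsWith(lines, PDB_CYCLIC_REMARK))
  if (!is.null(cyclic)) is_cyclic <- isTRUE(cyclic)
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atom)) abort_invalid("no ATOM records found")
  fields <- data.frame(
    name = trimws(substr(atom, 13, 16)),
    altloc = substr(atom, 17, 17),
    chain = substr(atom, 22, 22),
    resseq = as.integer(substr(atom, 23, 26)),
    icode = substr(atom, 27, 27),
    x = as.numeric(substr(atom, 31, 38)),
    y = as.numeric(substr(atom, 39, 46)),
    z = as.numeric(substr(atom, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(atom, 55, 60))),
    stringsAsFactors = FALSE
  )
  fields$occ[is.na(fields$occ)] <- 1
  chains <- unique(fields$chain)
  if (length(chains) > 1) {
    if (is.null(chain)) {
      abort_invalid(sprintf("multiple chains (%s); select one with `chain`",
                            paste(chains, collapse = ", ")))
    }
    fields <- fields[fields$chain == chain, , drop = FALSE]
    if (!nrow(fields)) abort_invalid(sprintf("no ATOM records for chain %s", chain))
  }
  if (any(fields$icode != " ")) abort_invalid("insertion codes are not supported")
  fields <- fields[fields$name %in% BACKBONE_ATOMS, , drop = FALSE]
  # resolve altlocs: highest occupancy, then first occurrence
  fields <- fields[order(fields$resseq, match(fields$name, BACKBONE_ATOMS),
                         -fields$occ), , drop = FALSE]
  fields <- fields[!duplicated(fields[, c("resseq", "name")]), , drop = FALSE]
  res_ids <- sort(unique(fields$resseq))
  L <- length(res_ids)
  mats <- lapply(BACKBONE_ATOMS, function(a) matrix(NA_real_, L, 3))
  names(mats) <- BACKBONE_ATOMS
  for (r in seq_len(L)) {
    sub <- fields[fields$resseq == res_ids[r], , drop = FALSE]
    for (a in BACKBONE_ATOMS) {
      row <- sub[sub$name == a, , drop = FALSE]
      if (nrow(row)) mats[[a]][r, ] <- c(row$x[1], row$y[1], row$z[1])
    }
  }
  # tolerate a missing carbonyl O on the final residue of linear chains
  if (!is_cyclic && anyNA(mats$O[L, ]) &&
      !anyNA(mats$N[L, ]) && !anyNA(mats$CA[L, ]) && !anyNA(mats$C[L, ])) {
    g <- ideal_geometry()
    ref <- if (L > 1) mats$N[L - 1, ] else mats$N[L, ] + c(1, 0, 0)
    mats$O[L, ] <- place_atom(ref, mats$CA[L, ], mats$C[L, ], g$c_o, g$ca_c_o, 0)
    warning("missing O on final residue rebuilt from ideal geometry")
  }
  for (a in BACKBONE_ATOMS) {
    bad <- which(apply(mats[[a]], 1, anyNA))
    if (length(bad)) {
      abort_invalid(sprintf("residue %d is missing atom %s", res_ids[bad[1]], a))
    }
  }
  backbone(mats$N, mats$CA, mats$C, mats$O, cyclic = is_cyclic,
           id = sub("\\.pdb$", "", basename(path)))
}

#' Read / write FASTA
#'
#' Plain FASTA with 80-column wrapping; ids are preserved verbatim.
#' Lowercase letters are upcased with a warning on read; duplicate ids
#' are an error.
#'
#' @param path file path.
#' @return `read_fasta` returns a named character vector (names = ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) abort_invalid("FASTA must start with a '>' header")
  ids <- sub("^>", "", lines[hdr])
  if (anyDuplicated(ids)) {
    abort_invalid(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  out[unique(grp)] <- seqs
  if (any(grepl("[a-z]", out))) {
    warning("lowercase letters upcased")
    out <- toupper(out)
  }
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) abort_invalid("duplicate sequence ids")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(1, nchar(s)), by = 80)
    writeLines(substring(s, starts, pmin(starts + 79, nchar(s))), con)
  }
  invisible(path)
}

# TSV with a schema-version comment line; deterministic output.
write_tsv_versioned <- function(df, path, schema = "cyclicdesign-tsv-v1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema: %s", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_versioned <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE) |>
    tibble::as_tibble()
}
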