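# Invariant featurization of a backbone as a residue graph: k nearest
# neighbours by CA distance, RBF-encoded inter-atom distances and cyclic
# relative positional offsets.

#' The canonical amino-acid alphabet
#'
#' The 20 canonical L-amino acids in fixed alphabetical one-letter order;
#' all sequence tensors index into this order.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Cyclic relative positional offset
#'
#' For a macrocycle the separation between residues i and j is the signed
#' minimal distance around the ring, `((j - i + floor(L/2)) mod L) -
#' floor(L/2)`, rather than the linear index difference; for even L the
#' antipodal tie resolves to `-L/2`. The result is clipped to
#' `[-d_max, d_max]`.
#'
#' @param i,j 0-based residue indices (vectorised).
#' @param L ring length.
#' @param d_max clip bound (default 32).
#' @param cyclic if `FALSE`, the plain clipped difference `j - i`.
#' @return integer offsets.
#' @export
cyclic_offset <- function(i, j, L, d_max = 32, cyclic = TRUE) {
  if (any(i < 0 | i >= L | j < 0 | j >= L)) {
    abort_invalid("indices must lie in [0, L)")
  }
  d <- if (cyclic) ((j - i + L %/% 2) %% L) - L %/% 2 else j - i
  as.integer(pmin(pmax(d, -d_max), d_max))
}

#' Model configuration
#'
#' Architecture of the message-passing sequence design model. Defaults
#' mirror the published base model: hidden width 128, three encoder and
#' three decoder layers, 16 radial basis functions spanning 2-22 Angstrom,
#' up to 32 neighbours.
#'
#' @param hidden_dim node/edge embedding width.
#' @param enc_layers,dec_layers message-passing depths.
#' @param k_neighbors neighbours per residue (clamped to L-1 at
#'   featurization time).
#' @param n_rbf radial basis count.
#' @param rbf_min,rbf_max RBF center range in Angstrom.
#' @param d_max positional offset clip.
#' @param cyclic use ring-aware relative positions (default TRUE).
#' @param dropout dropout rate used during training.
#' @return an object of class `model_config`.
#' @export
model_config <- function(hidden_dim = 128, enc_layers = 3, dec_layers = 3,
                         k_neighbors = 32, n_rbf = 16, rbf_min = 2,
                         rbf_max = 22, d_max = 32, cyclic = TRUE,
                         dropout = 0) {
  if (hidden_dim < 1 || enc_layers < 1 || dec_layers < 1 || n_rbf < 1) {
    abort_invalid("model dimensions must be positive")
  }
  structure(
    list(
      hidden_dim = as.integer(hidden_dim),
      enc_layers = as.integer(enc_layers),
      dec_layers = as.integer(dec_layers),
      k_neighbors = as.integer(k_neighbors),
      n_rbf = as.integer(n_rbf), rbf_min = rbf_min, rbf_max = rbf_max,
      d_max = as.integer(d_max), cyclic = isTRUE(cyclic),
      alphabet = AA_ALPHABET, dropout = dropout
    ),
    class = "model_config"
  )
}

# Virtual CB from N/CA/C by the standard chiral tetrahedral construction;
# breaks mirror symmetry so distance features can tell phi from -phi.
virtual_cb <- function(bb) {
  b <- bb$CA - bb$N
  c <- bb$C - bb$CA
  a <- cbind(
    b[, 2] * c[, 3] - b[, 3] * c[, 2],
    b[, 3] * c[, 1] - b[, 1] * c[, 3],
    b[, 1] * c[, 2] - b[, 2] * c[, 1]
  )
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c + bb$CA
}

#' Featurize a backbone as a residue graph
#'
#' k nearest neighbours by CA distance (self excluded); each directed edge
#' carries the RBF encodings of the 25 ordered inter-atom distances over
#' {N, CA, C, O, virtual CB} of the two residues, concatenated with a
#' one-hot cyclic positional offset. All features are functions of
#' pairwise geometry only, hence rigid-motion invariant.
#'
#' @param bb a [backbone()].
#' @param config a [model_config()].
#' @return a list of class `graph_features`: `edge_feat` ((L*k) x F
#'   matrix, edges ordered residue-major), `i_idx`, `j_idx` (1-based
#'   endpoint indices), `k`, `L`, `n_feat`.
#' @export
featurize <- function(bb, config = model_config()) {
  L <- length(bb)
  if (L < 3) abort_invalid("need at least 3 residues")
  k <- min(config$k_neighbors, L - 1L)
  D <- as.matrix(stats::dist(bb$CA))
  diag(D) <- Inf
  nbr <- t(apply(D, 1, function(row) order(row)[seq_len(k)]))
  i_idx <- rep(seq_len(L), each = k)
  j_idx <- as.integer(t(nbr))
  atoms <- list(bb$N, bb$CA, bb$C, bb$O, virtual_cb(bb))
  n_pair <- 25L
  centers <- seq(config$rbf_min, config$rbf_max, length.out = config$n_rbf)
  sigma <- (config$rbf_max - config$rbf_min) / config$n_rbf
  n_off <- 2L * config$d_max + 1L
  F_dim <- n_pair * config$n_rbf + n_off
  edge_feat <- matrix(0, L * k, F_dim)
  col <- 0L
  for (ai in 1:5) {
    for (aj in 1:5) {
      dij <- sqrt(rowSums((atoms[[ai]][i_idx, , drop = FALSE] -
                             atoms[[aj]][j_idx, , drop = FALSE])^2))
      rbf <- exp(-((outer(dij, centers, `-`)) / sigma)^2)
      edge_feat[, col + seq_len(config$n_rbf)] <- rbf
      col <- col + config$n_rbf
    }
  }
  off <- cyclic_offset(i_idx - 1L, j_idx - 1L, L, config$d_max, config$cyclic)
  edge_feat[cbind(seq_len(L * k), n_pair * config$n_rbf + off + config$d_max + 1L)] <- 1
  structure(
    list(edge_feat = edge_feat, i_idx = i_idx, j_idx = j_idx, k = k, L = L,
         n_feat = F_dim),
    class = "graph_features"
  )
}
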