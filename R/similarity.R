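#' GIP kernel bandwidth from interaction profiles
#'
#' The Gaussian interaction profile (GIP) kernel bandwidth is set from the
#' data as `gamma = n / sum_i ||y_i||^2`, i.e. the reciprocal of the mean
#' squared profile norm. This is the standard normalisation for GIP
#' kernels on interaction data: it makes the kernel scale-free with
#' respect to the overall density of the association matrix.
#'
#' @param profiles 0/1 matrix, one interaction profile per row (see
#'   [to_profile_matrix()]).
#' @return positive scalar bandwidth.
#' @export
gip_bandwidth <- function(profiles) {
  profiles <- as.matrix(profiles)
  ssq <- sum(profiles^2)
  if (ssq == 0) stop("all interaction profiles are zero; GIP bandwidth undefined")
  nrow(profiles) / ssq
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes `S[i, j] = exp(-gamma * ||y_i - y_j||^2)` for every pair of
#' profile rows. The result is symmetric with unit diagonal and entries in
#' (0, 1].
#'
#' @param profiles 0/1 matrix, one profile per row, with row labels.
#' @param gamma bandwidth; defaults to [gip_bandwidth()] of `profiles`.
#' @return a [similarity_matrix()].
#' @export
gip_kernel <- function(profiles, gamma = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(gamma)) gamma <- gip_bandwidth(profiles)
  if (gamma <= 0) stop("GIP bandwidth must be positive")
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical guard
  s <- exp(-gamma * d2)
  diag(s) <- 1
  labs <- rownames(profiles)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(profiles)))
  similarity_matrix(s, labs, check_diagonal = TRUE)
}

#' Integrate a primary similarity matrix with its GIP complement
#'
#' Entries with non-zero primary (semantic or functional) similarity are
#' retained unchanged; zero entries — where the primary source carries no
#' information — are filled with the GIP kernel value. The diagonal is
#' forced to 1. Applying the rule twice with the same GIP matrix is a
#' no-op.
#'
#' @param primary semantic (disease) or functional (miRNA) similarity.
#' @param gip GIP kernel similarity with identical labels in identical
#'   order.
#' @return the integrated [similarity_matrix()].
#' @export
integrate_similarity <- function(primary, gip) {
  if (!identical(rownames(primary), rownames(gip)))
    stop("label mismatch between primary and GIP similarity matrices")
  p <- unclass(as.matrix(primary))
  g <- unclass(as.matrix(gip))
  out <- ifelse(p > 0, p, g)
  diag(out) <- 1
  similarity_matrix(out, rownames(primary), check_diagonal = TRUE)
}

#' Assemble raw node features for the heterogeneous graph
#'
#' Each node (diseases first, then miRNAs, matching graph node order) gets
#' the concatenation of: its row of the integrated disease similarity
#' (zeros for miRNA nodes), its row of the integrated miRNA similarity
#' (zeros for disease nodes), its topological embedding, and a two-bit
#' node-type one-hot. The learnable projection to the model's hidden width
#' is part of the model, not of this assembly, so features here keep their
#' raw width `n_D + n_M + embed_dim + 2`.
#'
#' @param i_d integrated disease similarity (`n_D x n_D`).
#' @param i_m integrated miRNA similarity (`n_M x n_M`).
#' @param topo embedding matrix with one row per node in graph node order
#'   (diseases then miRNAs), e.g. from [node2vec_embed()].
#' @return numeric matrix `(n_D + n_M) x (n_D + n_M + embed_dim + 2)` with
#'   node labels as rownames.
#' @export
build_node_features <- function(i_d, i_m, topo) {
  i_d <- unclass(as.matrix(i_d)); i_m <- unclass(as.matrix(i_m))
  nd <- nrow(i_d); nm <- nrow(i_m)
  topo <- as.matrix(topo)
  if (nrow(topo) != nd + nm)
    stop("embedding has ", nrow(topo), " rows; expected ", nd + nm, " (diseases then miRNAs)")
  feats <- matrix(0, nd + nm, nd + nm + ncol(topo) + 2L)
  feats[seq_len(nd), seq_len(nd)] <- i_d
  feats[nd + seq_len(nm), nd + seq_len(nm)] <- i_m
  feats[, nd + nm + seq_len(ncol(topo))] <- topo
  feats[seq_len(nd), nd + nm + ncol(topo) + 1L] <- 1
  feats[nd + seq_len(nm), nd + nm + ncol(topo) + 2L] <- 1
  rownames(feats) <- c(rownames(i_d), rownames(i_m))
  feats
}
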