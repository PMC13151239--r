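#' Build the bidirected miRNA-disease heterogeneous graph
#'
#' Nodes are diseases `1..n_D` followed by miRNAs `n_D+1..n_D+n_M`. Every
#' known association (d, m) contributes the directed edge d -> m and its
#' reverse m -> d, so information flows both ways; there are no
#' within-type edges and no self-loops.
#'
#' @param assoc an [association_table()].
#' @return an object of class `"hetero_graph"` with `n_diseases`,
#'   `n_mirnas`, `node_ids`, and `edges` (2-column integer matrix of
#'   directed node pairs).
#' @export
build_graph <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_table"))
  if (nrow(assoc$pairs) == 0L) stop("association table has no pairs")
  nd <- length(assoc$disease_ids)
  d <- assoc$pairs[, "disease"]
  m <- assoc$pairs[, "mirna"] + nd
  structure(
    list(n_diseases = nd,
         n_mirnas = length(assoc$mirna_ids),
         node_ids = c(assoc$disease_ids, assoc$mirna_ids),
         edges = cbind(from = c(d, m), to = c(m, d))),
    class = "hetero_graph")
}

#' @export
#' @method print hetero_graph
print.hetero_graph <- function(x, ...) {
  cat(sprintf("heterogeneous graph: %d nodes (%d diseases + %d miRNAs), %d directed edges\n",
              x$n_diseases + x$n_mirnas, x$n_diseases, x$n_mirnas, nrow(x$edges)))
  invisible(x)
}

#' Symmetrically normalized adjacency matrix
#'
#' Returns the degree-normalized adjacency `A~ = D^{-1/2} A D^{-1/2}` of
#' the bidirected graph as a sparse matrix, so that the entry for an edge
#' (i, j) is `1 / sqrt(deg_i * deg_j)`. No self-loops are added — the
#' residual term in the node update already carries self information.
#' Isolated nodes simply get zero rows (not an error).
#'
#' @param g a [build_graph()] result.
#' @param drop_pairs optional 2-column matrix of (disease index, miRNA
#'   index) pairs whose edges are removed before normalization. Used by
#'   the strict hold-out mode in which test-fold associations are also
#'   excluded from message passing.
#' @return a sparse symmetric `dgCMatrix` of size `n_nodes x n_nodes`.
#' @export
normalize_adjacency <- function(g, drop_pairs = NULL) {
  stopifnot(inherits(g, "hetero_graph"))
  n <- g$n_diseases + g$n_mirnas
  e <- g$edges
  if (!is.null(drop_pairs) && nrow(drop_pairs) > 0L) {
    drop_from <- c(drop_pairs[, 1L], drop_pairs[, 2L] + g$n_diseases)
    drop_to <- c(drop_pairs[, 2L] + g$n_diseases, drop_pairs[, 1L])
    keep <- !(paste(e[, 1L], e[, 2L]) %in% paste(drop_from, drop_to))
    e <- e[keep, , drop = FALSE]
  }
  if (nrow(e) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n)))
  a <- Matrix::sparseMatrix(i = e[, 1L], j = e[, 2L], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(a)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv)
}

#' Sample negative (unconfirmed) disease-miRNA pairs
#'
#' Draws `n` distinct pairs uniformly from the complement of the known
#' association set over the full disease x miRNA universe. Sampling
#' happens once, globally, before cross-validation folds are formed, and
#' is reproducible under `seed`.
#'
#' @param assoc an [association_table()].
#' @param n number of negatives; the convention is `n = nrow(assoc$pairs)`
#'   (balanced classes).
#' @param seed integer RNG seed.
#' @return 2-column integer matrix (`disease`, `mirna`).
#' @export
sample_negatives <- function(assoc, n, seed) {
  stopifnot(inherits(assoc, "assoc_table"))
  nd <- length(assoc$disease_ids)
  nm <- length(assoc$mirna_ids)
  pos_key <- (assoc$pairs[, "disease"] - 1) * nm + assoc$pairs[, "mirna"]
  n_free <- nd * nm - length(pos_key)
  if (n > n_free)
    stop("requested ", n, " negatives but only ", n_free, " unconfirmed pairs exist")
  neg_key <- local_seed(seed, {
    if (n_free <= 2e6) {
      pool <- setdiff(seq_len(nd * nm), pos_key)
      pool[sample.int(length(pool), n)]
    } else {
      # rejection sampling for very large universes
      got <- integer(0)
      while (length(got) < n) {
        cand <- sample.int(nd * nm, n - length(got), replace = TRUE)
        cand <- setdiff(unique(cand), c(pos_key, got))
        got <- c(got, cand)
      }
      got[seq_len(n)]
    }
  })
  cbind(disease = (neg_key - 1L) %/% nm + 1L, mirna = (neg_key - 1L) %% nm + 1L)
}

#' Partition positive and negative samples into cross-validation folds
#'
#' Both sample sets are split at the association level into `k` near-equal
#' folds (sizes differing by at most one, earlier folds absorbing the
#' remainder); negatives are assigned by the same shuffling procedure and
#' seed stream as positives so the two partitions are formed together.
#'
#' @param positives,negatives 2-column integer matrices of (disease,
#'   miRNA) index pairs.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @return an object of class `"sample_partition"`: `positives`,
#'   `negatives`, `fold_pos`, `fold_neg` (fold index 1..k per sample),
#'   `k`.
#' @export
make_folds <- function(positives, negatives, k = 5, seed = 1234) {
  if (k < 2) stop("k must be at least 2")
  np <- nrow(positives); nn <- nrow(negatives)
  if (np < k || nn < k) stop("fewer samples than folds")
  assign_folds <- function(n) {
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    rep(seq_len(k), sizes)[sample.int(n)]
  }
  folds <- local_seed(seed, list(pos = assign_folds(np), neg = assign_folds(nn)))
  structure(
    list(positives = positives, negatives = negatives,
         fold_pos = folds$pos, fold_neg = folds$neg, k = as.integer(k)),
    class = "sample_partition")
}

#' @export
#' @method print sample_partition
print.sample_partition <- function(x, ...) {
  cat(sprintf("sample partition: %d positives + %d negatives in %d folds\n",
              nrow(x$positives), nrow(x$negatives), x$k))
  invisible(x)
}

#' Export a sample partition as TSV
#'
#' One row per sample: disease id, miRNA id, label (1 positive, 0
#' negative) and fold index.
#'
#' @param partition a [make_folds()] result.
#' @param assoc the [association_table()] providing identifier labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, assoc, path) {
  stopifnot(inherits(partition, "sample_partition"), inherits(assoc, "assoc_table"))
  rows <- c(
    paste("disease", "mirna", "label", "fold", sep = "\t"),
    paste(assoc$disease_ids[partition$positives[, 1L]],
          assoc$mirna_ids[partition$positives[, 2L]], 1L, partition$fold_pos, sep = "\t"),
    paste(assoc$disease_ids[partition$negatives[, 1L]],
          assoc$mirna_ids[partition$negatives[, 2L]], 0L, partition$fold_neg, sep = "\t"))
  writeLines(rows, path)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
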