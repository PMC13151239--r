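#' Node2vec topological embeddings of the heterogeneous graph
#'
#' Samples biased second-order random walks over the (undirected view of
#' the) bidirected graph and trains a skip-gram model with negative
#' sampling on the resulting node sequences. Return/in-out bias follows
#' the usual node2vec scheme: stepping back to the previous node is
#' weighted `1/p`, moving to a common neighbour of the previous node is
#' weighted 1, and moving outward is weighted `1/q`; with `p = q = 1`
#' walks are uniform.
#'
#' Training is plain single-threaded SGD (linearly decaying learning
#' rate, unigram^0.75 negative-sampling distribution, dynamic window),
#' so results are reproducible under `seed`. Isolated nodes never appear
#' in a walk and receive an all-zero embedding row.
#'
#' @param g a [build_graph()] result.
#' @param dim embedding dimensionality (default 64).
#' @param p,q return and in-out bias parameters (default 1, 1).
#' @param walk_length nodes per walk (default 80).
#' @param n_walks walks started per node (default 10).
#' @param window maximum skip-gram window; the effective window per
#'   position is drawn uniformly from `1..window` (default 5).
#' @param n_neg negative samples per (centre, context) pair (default 5).
#' @param iters passes over the walk corpus (default 5).
#' @param alpha initial learning rate.
#' @param seed integer RNG seed.
#' @return numeric matrix `(n_nodes x dim)`, rows in graph node order,
#'   rownames = node ids.
#' @export
node2vec_embed <- function(g, dim = 64, p = 1, q = 1, walk_length = 80,
                           n_walks = 10, window = 5, n_neg = 5, iters = 5,
                           alpha = 0.025, seed = 1234) {
  stopifnot(inherits(g, "hetero_graph"))
  if (dim <= 0) stop("embedding dimension must be positive")
  n <- g$n_diseases + g$n_mirnas
  nb <- neighbour_list(g$edges, n)
  res <- local_seed(seed, {
    walks <- if (p == 1 && q == 1) n2v_walks_uniform(nb, n_walks, walk_length)
             else n2v_walks_biased(nb, n_walks, walk_length, p, q)
    if (nrow(walks) == 0L) list(emb = matrix(0, 0, dim), seen = integer(0))
    else {
      pairs <- walk_pairs(walks, window)
      emb <- sgns_train(pairs$centres, pairs$contexts, n, dim, n_neg, iters, alpha)
      list(emb = emb, seen = sort(unique(as.integer(walks))))
    }
  })
  out <- matrix(0, n, dim, dimnames = list(g$node_ids, NULL))
  if (length(res$seen) > 0L) out[res$seen, ] <- res$emb[res$seen, ]
  out
}

neighbour_list <- function(edges, n) {
  und <- unique(rbind(edges, edges[, 2:1]))
  split(und[, 2L], factor(und[, 1L], levels = seq_len(n)))
}

# Uniform (p = q = 1) first-order walks, vectorised across all walks:
# neighbour lists are flattened CSR-style and every step advances all
# walks at once. Returns a (n_active_walks x walk_length) matrix.
n2v_walks_uniform <- function(nb, n_walks, walk_length) {
  deg <- lengths(nb)
  flat <- unlist(nb, use.names = FALSE)
  ptr <- c(0L, cumsum(deg))          # 0-based offsets into flat
  starts <- rep(which(deg > 0L), times = n_walks)
  if (length(starts) == 0L) return(matrix(integer(0), 0, walk_length))
  w <- matrix(0L, length(starts), walk_length)
  cur <- starts
  w[, 1L] <- cur
  for (s in 2:walk_length) {
    pick <- ptr[cur] + pmin(floor(stats::runif(length(cur)) * deg[cur]), deg[cur] - 1L)
    cur <- flat[pick + 1L]
    w[, s] <- cur
  }
  w
}

# General biased second-order walks (slow path, used when p or q != 1).
n2v_walks_biased <- function(nb, n_walks, walk_length, p, q) {
  n <- length(nb)
  degs <- lengths(nb)
  active <- which(degs > 0L)
  walks <- matrix(0L, length(active) * n_walks, walk_length)
  wi <- 0L
  for (iter in seq_len(n_walks)) {
    for (v0 in active) {
      walk <- integer(walk_length)
      walk[1L] <- v0
      prev <- 0L
      v <- v0
      for (s in 2:walk_length) {
        ni <- nb[[v]]
        if (prev == 0L) {
          nxt <- ni[sample.int(length(ni), 1L)]
        } else {
          w <- ifelse(ni == prev, 1 / p, ifelse(ni %in% nb[[prev]], 1, 1 / q))
          nxt <- ni[sample.int(length(ni), 1L, prob = w)]
        }
        walk[s] <- nxt
        prev <- v
        v <- nxt
      }
      wi <- wi + 1L
      walks[wi, ] <- walk
    }
  }
  walks[seq_len(wi), , drop = FALSE]
}

# (centre, context) pairs under a dynamic window: each centre position
# draws an effective radius uniformly from 1..window and pairs with every
# position within it.
walk_pairs <- function(walks, window) {
  L <- ncol(walks)
  r <- matrix(sample.int(window, length(walks), replace = TRUE),
              nrow(walks), L)
  cl <- list(); xl <- list(); z <- 0L
  for (o in seq_len(window)) {
    if (o >= L) break
    ok <- r >= o
    for (i in seq_len(L - o)) {
      sel <- which(ok[, i])           # centre i, context i + o
      if (length(sel)) {
        z <- z + 1L; cl[[z]] <- walks[sel, i]; xl[[z]] <- walks[sel, i + o]
      }
      sel <- which(ok[, i + o])       # centre i + o, context i
      if (length(sel)) {
        z <- z + 1L; cl[[z]] <- walks[sel, i + o]; xl[[z]] <- walks[sel, i]
      }
    }
  }
  list(centres = unlist(cl, use.names = FALSE),
       contexts = unlist(xl, use.names = FALSE))
}

# Skip-gram with negative sampling (compiled inner loop).
sgns_train <- function(centres, contexts, n, dim, n_neg, iters, alpha) {
  counts <- tabulate(contexts, nbins = n)
  neg_prob <- counts^0.75
  neg_cdf <- cumsum(neg_prob / sum(neg_prob))
  w_in <- matrix(stats::runif(n * dim, -0.5, 0.5) / dim, n, dim)
  sgns_train_cpp(centres, contexts, n, dim, n_neg, iters, alpha, neg_cdf, w_in)
}

#' Write / read an embedding matrix as labelled TSV
#'
#' Convenience cache so embeddings are computed once per graph and seed.
#'
#' @param emb embedding matrix with rownames.
#' @param path file path.
#' @return `path` (write) or the embedding matrix (read).
#' @export
write_embedding <- function(emb, path) {
  header <- paste(c("node", paste0("e", seq_len(ncol(emb)))), collapse = "\t")
  body <- vapply(seq_len(nrow(emb)), function(i)
    paste(c(rownames(emb)[i], format(emb[i, ], digits = 17, trim = TRUE)), collapse = "\t"),
    character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(df[[1L]], NULL)
  m
}
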