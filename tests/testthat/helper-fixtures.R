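# Small programmatic fixtures shared across tests.

# 3 diseases x 4 miRNAs with a fixed pair set
tiny_assoc <- function() {
  association_table(data.frame(
    d = c("dA", "dA", "dB", "dC", "dC"),
    m = c("m1", "m2", "m1", "m3", "m4")))
}

# random bipartite association table with every node guaranteed a degree
random_assoc <- function(nd, nm, p = 0.3, seed = 1) {
  local_seed_test(seed, {
    amat <- matrix(stats::rbinom(nd * nm, 1, p), nd, nm)
    for (i in seq_len(nd)) if (sum(amat[i, ]) == 0) amat[i, sample.int(nm, 1)] <- 1
    for (j in seq_len(nm)) if (sum(amat[, j]) == 0) amat[sample.int(nd, 1), j] <- 1
    idx <- which(amat == 1, arr.ind = TRUE)
    association_table(
      data.frame(sprintf("d%02d", idx[, 1]), sprintf("m%02d", idx[, 2])),
      disease_levels = sprintf("d%02d", seq_len(nd)),
      mirna_levels = sprintf("m%02d", seq_len(nm)))
  })
}

local_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

# brute-force raw-moment oracle: per-node, per-neighbour, per-order loop
raw_moments_oracle <- function(h, adj, m_max) {
  adj <- as.matrix(adj)
  n <- nrow(h); f <- ncol(h)
  out <- lapply(seq_len(m_max), function(k) matrix(0, n, f))
  for (k in seq_len(m_max))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (adj[i, j] != 0)
          out[[k]][i, ] <- out[[k]][i, ] + adj[i, j] * h[j, ]^k
  out
}

# brute-force all-pairs AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# a small config that keeps unit tests fast; `...` overrides the defaults
fast_config <- function(...) {
  args <- list(hidden_dim = 16, embed_dim = 16, epochs = 10,
               n2v_walks = 3, n2v_walk_length = 15, n2v_iters = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(magmda_config, args)
}
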