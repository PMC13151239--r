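#' Raw multi-order neighbourhood moments
#'
#' For every node i, order k and feature column f, computes the weighted
#' neighbourhood moment
#' `m[i, f, k] = sum_j adj[i, j] * H[j, f]^k`,
#' i.e. elementwise k-th powers of neighbour features aggregated with the
#' normalized adjacency weights. Order 1 is ordinary mean-style message
#' passing `adj %*% H`.
#'
#' @param h numeric node-feature matrix (`n_nodes x n_features`).
#' @param adj normalized adjacency (dense or sparse `n_nodes x n_nodes`).
#' @param m_max maximum moment order (>= 1).
#' @return list of length `m_max`; element k is the `n x f` matrix of
#'   order-k moments.
#' @export
compute_raw_moments <- function(h, adj, m_max = 10) {
  if (m_max < 1) stop("m_max must be >= 1")
  h <- as.matrix(h)
  hp <- h
  out <- vector("list", m_max)
  for (k in seq_len(m_max)) {
    out[[k]] <- as.matrix(adj %*% hp)
    if (k < m_max) hp <- hp * h
  }
  names(out) <- paste0("order", seq_len(m_max))
  out
}

#' Numerically stabilized multi-order neighbourhood moments
#'
#' High-order raw moments explode with `|h|^k`; this operation replaces
#' them with stabilized statistics of the neighbourhood feature
#' distribution:
#' \itemize{
#'   \item order 1: the neighbourhood mean `mu = adj %*% h` (untouched);
#'   \item order 2: an approximate variance
#'     `max(0, adj %*% h^2 - mu^2)` elementwise;
#'   \item orders k >= 3: standardized central moments
#'     `c_k[i] = sum_j adj[i,j] * ((h[j] - mu[i]) / s[i])^k` with
#'     `s = sqrt(order2 + eps)`, clipped to `[-clip, clip]` and
#'     compressed through the sign-preserving map `sign(c) * log(1 + |c|)`.
#' }
#' A constant neighbourhood therefore yields zero for all orders >= 2,
#' and a symmetric neighbourhood yields zero odd orders.
#'
#' @param h,adj,m_max as in [compute_raw_moments()].
#' @param eps variance floor inside the standardisation (default 1e-6).
#' @param clip clipping bound for standardized central moments
#'   (default 10).
#' @param orders integer vector of orders to return (default all
#'   `1..m_max`); unrequested orders are skipped but orders 1-2 are
#'   always computed internally since they define the standardisation.
#' @return list indexed like [compute_raw_moments()], with `NULL` for
#'   unrequested orders.
#' @export
stabilize_moments <- function(h, adj, m_max = 10, eps = 1e-6, clip = 10,
                              orders = NULL) {
  fw <- stab_moments_forward(as.matrix(h), adj,
                             orders = if (is.null(orders)) seq_len(m_max) else orders,
                             eps = eps, clip = clip)
  out <- vector("list", m_max)
  for (k in seq_len(m_max)) out[k] <- list(fw$m[[as.character(k)]])
  names(out) <- paste0("order", seq_len(m_max))
  out
}

# nonzero entries of a (sparse or dense) adjacency as (i, j, x) triplets
adj_triplets <- function(adj) {
  if (inherits(adj, "sparseMatrix")) {
    tm <- methods::as(adj, "TsparseMatrix")
    list(i = tm@i + 1L, j = tm@j + 1L, x = tm@x)
  } else {
    nz <- which(adj != 0, arr.ind = TRUE)
    list(i = nz[, 1L], j = nz[, 2L], x = adj[nz])
  }
}

# Forward pass with cache. Orders 1-2 use sparse matrix products; the
# standardized central moments for k >= 3 are accumulated directly over
# the adjacency's nonzero entries,
#   c_{i,k} = sum_j a_ij ((h_j - mu_i)/s_i)^k,
# which is numerically exact for constant neighbourhoods (no cancelling
# expansion) before the clip / log compression.
stab_moments_forward <- function(h, adj, orders, eps, clip) {
  orders <- sort(unique(as.integer(orders)))
  n <- nrow(h); f <- ncol(h)
  mu <- as.matrix(adj %*% h)
  r2 <- as.matrix(adj %*% (h * h))
  vraw <- r2 - mu^2
  m2 <- pmax(vraw, 0)
  s <- sqrt(m2 + eps)

  m <- list(); ck <- list(); uk <- list()
  tr <- NULL; zpow <- list()   # zpow[[p]] = z^p per edge, p = 1..maxk
  maxk <- max(orders)
  if (maxk >= 3L) {
    tr <- adj_triplets(adj)
    z <- (h[tr$j, , drop = FALSE] - mu[tr$i, , drop = FALSE]) /
      s[tr$i, , drop = FALSE]
    zpow[[1L]] <- z
    for (p in 2:maxk) zpow[[p]] <- zpow[[p - 1L]] * z
  }
  rowsum_full <- function(vals, grp) {
    out <- matrix(0, n, f)
    agg <- rowsum(vals, grp, reorder = FALSE)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  for (k in orders) {
    key <- as.character(k)
    if (k == 1L) { m[[key]] <- mu; next }
    if (k == 2L) { m[[key]] <- m2; next }
    cmat <- rowsum_full(tr$x * zpow[[k]], tr$i)
    umat <- pmin(pmax(cmat, -clip), clip)
    m[[key]] <- sign(umat) * log1p(abs(umat))
    ck[[key]] <- cmat; uk[[key]] <- umat
  }
  list(m = m, orders = orders, mu = mu, vraw = vraw, m2 = m2, s = s,
       ck = ck, uk = uk, tr = tr, zpow = zpow,
       eps = eps, clip = clip, adj = adj, h = h,
       rowsum_full = rowsum_full)
}

# Backward pass: `gm` is a list keyed by order (character) of gradients
# w.r.t. the stabilized moments; returns the gradient w.r.t. h.
# Assumes a symmetric adjacency (as produced by normalize_adjacency).
stab_moments_backward <- function(cache, gm) {
  n <- nrow(cache$mu); f <- ncol(cache$mu)
  zero <- function() matrix(0, n, f)
  dmu <- zero(); ds <- zero(); dm2 <- zero(); dh <- zero()
  tr <- cache$tr
  for (k in cache$orders) {
    key <- as.character(k)
    g <- gm[[key]]
    if (is.null(g)) next
    if (k == 1L) { dmu <- dmu + g; next }
    if (k == 2L) { dm2 <- dm2 + g; next }
    u <- cache$uk[[key]]
    dc <- g * (1 / (1 + abs(u))) * (abs(cache$ck[[key]]) <= cache$clip)
    # c_{i,k} = sum_e a_e z_e^k  with z_e = (h_j - mu_i)/s_i:
    #   dz_e = a_e k z_e^(k-1) dc_i ;  dh_j += dz_e/s_i ;
    #   dmu_i -= dz_e/s_i ;  ds_i -= dz_e z_e / s_i
    dz <- (k * tr$x) * zpow_at(cache, k - 1L) * dc[tr$i, , drop = FALSE]
    s_e <- cache$s[tr$i, , drop = FALSE]
    dze <- dz / s_e
    dh <- dh + cache$rowsum_full(dze, tr$j)
    dmu <- dmu - cache$rowsum_full(dze, tr$i)
    ds <- ds - cache$rowsum_full(dz * cache$zpow[[1L]] / s_e, tr$i)
  }
  dm2 <- dm2 + ds * 0.5 / cache$s
  dvraw <- dm2 * (cache$vraw > 0)
  # r2 = adj %*% h^2 and mu = adj %*% h (adj symmetric)
  dh <- dh + as.matrix(cache$adj %*% dvraw) * (2 * cache$h)
  dmu <- dmu - 2 * cache$mu * dvraw
  dh <- dh + as.matrix(cache$adj %*% dmu)
  dh
}

zpow_at <- function(cache, p) {
  if (p == 0L) 1 else cache$zpow[[p]]
}
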