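#' Sample moment-order weights from importance logits
#'
#' The layer carries a learnable importance logit per candidate moment
#' order. At inference the weights are the deterministic softmax of the
#' logits; during training a Gumbel-Softmax soft sample is drawn instead
#' (Gumbel noise added to the logits, softmax at `gumbel_temperature`),
#' which keeps the discrete-like selection differentiable. Weights sum to
#' 1 either way.
#'
#' @param order_logits numeric vector of length `m_max`.
#' @param mode `"infer"` (softmax) or `"train"` (Gumbel-Softmax sample).
#' @param gumbel_temperature positive softmax temperature used in train
#'   mode (default 1).
#' @param seed optional seed for the Gumbel draw; `NULL` uses (and
#'   advances) the current RNG stream.
#' @return numeric weight vector summing to 1.
#' @export
sample_order_weights <- function(order_logits, mode = c("infer", "train"),
                                 gumbel_temperature = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "infer") return(softmax_vec(order_logits))
  if (gumbel_temperature <= 0) stop("gumbel_temperature must be positive")
  gn <- if (is.null(seed)) gumbel_noise(length(order_logits)) else
    local_seed(seed, gumbel_noise(length(order_logits)))
  softmax_vec((order_logits + gn) / gumbel_temperature)
}

gumbel_noise <- function(n) -log(-log(stats::runif(n)))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Initialise a dynamic threshold network
#'
#' A small two-layer perceptron mapping the mean-pooled layer features to
#' a scalar gating threshold. With zero initialisation of the output
#' layer the threshold starts at `0.5 * tau_scale` regardless of the
#' input.
#'
#' @param input_dim width of the pooled feature vector.
#' @param hidden hidden width (default 16).
#' @param init `"zero"` (deterministic start) or `"glorot"`.
#' @return parameter list `W1`, `b1`, `w2`, `b2`.
#' @export
init_threshold_net <- function(input_dim, hidden = 16, init = c("zero", "glorot")) {
  init <- match.arg(init)
  W1 <- if (init == "zero") matrix(0, input_dim, hidden) else glorot(input_dim, hidden)
  list(W1 = W1, b1 = numeric(hidden), w2 = numeric(hidden), b2 = 0)
}

#' Dynamic gating threshold from pooled layer features
#'
#' Computes `tau = sigmoid(MLP(colMeans(H))) * tau_scale`: a single
#' scalar threshold per layer, shared across orders, living on the scale
#' of softmax order weights (`tau_scale` defaults to `2 / m_max` so a
#' uniform weight `1/m_max` sits at the centre of the reachable range).
#' Invariant to permutations of the node order by construction.
#'
#' @param h node-feature matrix of the current layer.
#' @param net threshold network parameters (see [init_threshold_net()]).
#' @param tau_scale upper bound of the threshold range.
#' @return scalar `tau` in `(0, tau_scale)`.
#' @export
dynamic_threshold <- function(h, net, tau_scale = 0.2) {
  pooled <- colMeans(as.matrix(h))
  a1 <- tanh(drop(pooled %*% net$W1) + net$b1)
  sigmoid(sum(a1 * net$w2) + net$b2) * tau_scale
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gate moment orders against the dynamic threshold
#'
#' Soft comparison of each order weight with the threshold:
#' `g_k = sigmoid((W_k - tau) / gamma)`. As `gamma -> 0` this becomes a
#' hard indicator `W_k > tau`; at `W_k = tau` the gate is exactly 0.5.
#'
#' @param w order weight vector (from [sample_order_weights()]).
#' @param tau scalar threshold (from [dynamic_threshold()]).
#' @param gamma positive gating temperature.
#' @return gate vector in (0, 1).
#' @export
gate_orders <- function(w, tau, gamma) {
  if (gamma <= 0) stop("gating temperature gamma must be positive")
  sigmoid((w - tau) / gamma)
}

#' Combine gates with a Top-K retention mask
#'
#' To prevent the gate from suppressing every order, only the K
#' largest-weight orders are retained (ties broken toward the lower
#' order) and the effective weight of order k is `g_k * mask_k`; masked
#' orders are exactly zero.
#'
#' @param g gate vector.
#' @param w order weight vector used for the Top-K ranking.
#' @param k retention size (default 5); `k >= length(w)` keeps all.
#' @return list with `w_eff` (effective weights) and `mask` (0/1
#'   vector with exactly `min(k, length(w))` ones).
#' @export
effective_weights <- function(g, w, k = 5) {
  if (k < 1) stop("k must be >= 1")
  m <- length(w)
  keep <- order(-w, seq_len(m))[seq_len(min(k, m))]
  mask <- numeric(m)
  mask[keep] <- 1
  list(w_eff = g * mask, mask = mask)
}

#' Cross-order attention over retained moment embeddings
#'
#' Each effectively weighted moment stack `w_eff[k] * moments[[k]]` is
#' projected by its per-order linear map into the hidden space, giving
#' candidate embeddings `z_k`. A scalar score per (node, order) is
#' computed — additively (`a' tanh(z)`) by default, or linearly
#' (`a' z`) — and normalized with a softmax across the *retained* orders
#' only, so masked orders receive attention exactly 0.
#'
#' @param moments list of moment matrices (from [stabilize_moments()]);
#'   entries for masked orders may be `NULL`.
#' @param w_eff effective weight vector (`w_eff[k] == 0` marks masked
#'   orders).
#' @param proj list with per-order projections `W` (list of `f x h`
#'   matrices) and `b` (list of length-`h` intercepts).
#' @param attn_vec length-`h` attention scoring vector.
#' @param type `"additive"` (tanh scoring) or `"linear"`.
#' @return list with `z` (list of `n x h` candidate embeddings, `NULL`
#'   when masked) and `attn` (`n x m_max` matrix of attention weights,
#'   rows summing to 1 over retained orders).
#' @export
cross_order_attention <- function(moments, w_eff, proj, attn_vec,
                                  type = c("additive", "linear")) {
  type <- match.arg(type)
  m <- length(w_eff)
  retained <- which(w_eff != 0)
  if (length(retained) == 0L) stop("no retained orders (all effective weights zero)")
  n <- nrow(moments[[retained[1L]]])
  z <- vector("list", m)
  sc <- matrix(-Inf, n, m)
  for (k in retained) {
    zk <- (w_eff[k] * moments[[k]]) %*% proj$W[[k]]
    zk <- sweep(zk, 2L, proj$b[[k]], `+`)
    z[[k]] <- zk
    sc[, k] <- if (type == "additive") tanh(zk) %*% attn_vec else zk %*% attn_vec
  }
  attn <- softmax_rows_masked(sc, retained)
  list(z = z, attn = attn)
}

softmax_rows_masked <- function(sc, retained) {
  out <- matrix(0, nrow(sc), ncol(sc))
  s <- sc[, retained, drop = FALSE]
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  out[, retained] <- e / rowSums(e)
  out
}

#' Residual node update from attention-weighted moment embeddings
#'
#' `H_next = act(sum_k attn[, k] * z_k + H)`: the attention-weighted sum
#' of candidate moment embeddings plus a residual copy of the current
#' representation, passed through a nonlinearity.
#'
#' @param h current node representations (`n x h`).
#' @param z candidate embedding list from [cross_order_attention()].
#' @param attn attention matrix from [cross_order_attention()].
#' @param act activation: `"elu"` (default), `"relu"`, or `"identity"`.
#' @return updated representations, same shape as `h`.
#' @export
update_nodes <- function(h, z, attn, act = c("elu", "relu", "identity")) {
  act <- match.arg(act)
  out <- h
  for (k in seq_along(z)) {
    if (is.null(z[[k]])) next
    if (ncol(z[[k]]) != ncol(h)) stop("candidate embedding width does not match node width")
    out <- out + attn[, k] * z[[k]]
  }
  activate(out, act)
}

activate <- function(x, act) {
  switch(act,
         elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
         relu = pmax(x, 0),
         identity = x)
}

activate_grad <- function(x, act) {
  switch(act,
         elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
         relu = (x > 0) * 1,
         identity = x * 0 + 1)
}

# ---- fused layer forward/backward used by the training loop ----------

# One AdaptiveMMConv layer. `lp` holds the layer parameters
# (alpha, threshold net W1/b1/w2/b2, per-order Wz/bz, attention vector a),
# `cfg` the model configuration. In train mode the Gumbel draw consumes
# the caller's RNG stream. Returns H_next and a cache for the backward
# pass.
layer_forward <- function(h, adj, lp, cfg, train = FALSE) {
  m_max <- cfg$m_max
  if (train) {
    gn <- gumbel_noise(m_max)
    w <- softmax_vec((lp$alpha + gn) / cfg$gumbel_tau)
    sm_scale <- 1 / cfg$gumbel_tau
  } else {
    w <- softmax_vec(lp$alpha)
    sm_scale <- 1
  }
  pooled <- colMeans(h)
  a1 <- tanh(drop(pooled %*% lp$W1) + lp$b1)
  traw <- sum(a1 * lp$w2) + lp$b2
  tsig <- sigmoid(traw)
  tau_scale <- 2 / m_max
  tau <- tsig * tau_scale
  g <- sigmoid((w - tau) / cfg$gate_gamma)
  ew <- effective_weights(g, w, cfg$top_k)
  if (isTRUE(cfg$scale_weights)) ew$w_eff <- ew$w_eff * w
  retained <- which(ew$mask == 1)
  mom <- stab_moments_forward(h, adj, orders = retained, eps = cfg$eps, clip = cfg$clip)

  n <- nrow(h)
  z <- vector("list", m_max)
  tn <- vector("list", m_max)
  x <- vector("list", m_max)
  sc <- matrix(-Inf, n, m_max)
  additive <- identical(cfg$attention, "additive")
  for (k in retained) {
    x[[k]] <- ew$w_eff[k] * mom$m[[as.character(k)]]
    zk <- x[[k]] %*% lp$Wz[[k]]
    zk <- sweep(zk, 2L, lp$bz[[k]], `+`)
    z[[k]] <- zk
    if (additive) {
      tn[[k]] <- tanh(zk)
      sc[, k] <- tn[[k]] %*% lp$a
    } else {
      sc[, k] <- zk %*% lp$a
    }
  }
  attn <- softmax_rows_masked(sc, retained)
  out <- h
  for (k in retained) out <- out + attn[, k] * z[[k]]
  hn <- activate(out, cfg$act)
  list(h_next = hn,
       cache = list(h = h, pooled = pooled, a1 = a1, tsig = tsig,
                    tau = tau, tau_scale = tau_scale, w = w, g = g,
                    sm_scale = sm_scale, mask = ew$mask, w_eff = ew$w_eff,
                    retained = retained, mom = mom, x = x, z = z, tn = tn,
                    attn = attn, pre = out, additive = additive))
}

# Backward through one layer: `dhn` is the gradient w.r.t. h_next.
# Returns dh (gradient w.r.t. the layer input) and the parameter
# gradients in the same shape as `lp`.
layer_backward <- function(dhn, cache, lp, cfg) {
  h <- cache$h
  n <- nrow(h); hidden <- ncol(h)
  retained <- cache$retained
  dpre <- dhn * activate_grad(cache$pre, cfg$act)
  dh <- dpre                                  # residual path
  dattn <- matrix(0, n, cfg$m_max)
  dz <- vector("list", cfg$m_max)
  for (k in retained) {
    dattn[, k] <- rowSums(dpre * cache$z[[k]])
    dz[[k]] <- cache$attn[, k] * dpre
  }
  # softmax (per row, over retained orders)
  ar <- cache$attn[, retained, drop = FALSE]
  dar <- dattn[, retained, drop = FALSE]
  dsc_r <- ar * (dar - rowSums(dar * ar))
  da <- numeric(hidden)
  for (j in seq_along(retained)) {
    k <- retained[j]
    if (cache$additive) {
      da <- da + drop(crossprod(cache$tn[[k]], dsc_r[, j]))
      dz[[k]] <- dz[[k]] + outer(dsc_r[, j], lp$a) * (1 - cache$tn[[k]]^2)
    } else {
      da <- da + drop(crossprod(cache$z[[k]], dsc_r[, j]))
      dz[[k]] <- dz[[k]] + outer(dsc_r[, j], lp$a)
    }
  }
  dWz <- rep(list(NULL), cfg$m_max)
  dbz <- rep(list(NULL), cfg$m_max)
  dwt <- numeric(cfg$m_max)
  gm <- list()
  for (k in retained) {
    dWz[[k]] <- crossprod(cache$x[[k]], dz[[k]])
    dbz[[k]] <- colSums(dz[[k]])
    dx <- tcrossprod(dz[[k]], lp$Wz[[k]])
    mk <- cache$mom$m[[as.character(k)]]
    dwt[k] <- sum(dx * mk)
    gm[[as.character(k)]] <- cache$w_eff[k] * dx
  }
  for (k in seq_len(cfg$m_max)) {
    if (is.null(dWz[[k]])) { dWz[[k]] <- 0 * lp$Wz[[k]]; dbz[[k]] <- 0 * lp$bz[[k]] }
  }
  dh <- dh + stab_moments_backward(cache$mom, gm)

  # gates: w_eff = g * mask (optionally * W)
  scale_w <- isTRUE(cfg$scale_weights)
  dg <- dwt * cache$mask * (if (scale_w) cache$w else 1)
  gg <- cache$g * (1 - cache$g) / cfg$gate_gamma
  dw_gate <- dg * gg
  if (scale_w) dw_gate <- dw_gate + dwt * cache$mask * cache$g
  dtau <- -sum(dg * gg)
  # threshold net
  dtsig <- dtau * cache$tau_scale
  dtraw <- dtsig * cache$tsig * (1 - cache$tsig)
  dw2 <- cache$a1 * dtraw
  db2 <- dtraw
  da1 <- dtraw * lp$w2
  dz1 <- da1 * (1 - cache$a1^2)
  dW1 <- outer(cache$pooled, dz1)
  db1 <- dz1
  dpooled <- drop(lp$W1 %*% dz1)
  dh <- dh + matrix(dpooled / n, n, hidden, byrow = TRUE)
  # order weights -> logits (softmax Jacobian, scaled by 1/gumbel_tau in train)
  dalpha <- cache$w * (dw_gate - sum(dw_gate * cache$w)) * cache$sm_scale
  list(dh = dh,
       grads = list(alpha = dalpha, W1 = dW1, b1 = db1, w2 = dw2, b2 = db2,
                    Wz = dWz, bz = dbz, a = da))
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}
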