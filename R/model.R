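#' Model configuration
#'
#' Collects every tunable of the association model with the reference
#' defaults: Adam with learning rate 5e-5 and weight decay 1e-3, hidden
#' width 64, two adaptive moment convolution layers, a candidate moment
#' pool of `m_max = 10` with Top-K retention `top_k = 5`, dropout 0.3
#' (pair representation) and 0.2 (input features / hidden states), and a
#' fixed seed of 1234.
#'
#' @param hidden_dim hidden representation width.
#' @param n_layers number of adaptive moment convolution layers.
#' @param m_max maximum candidate moment order.
#' @param top_k Top-K retention size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay folded into the gradient.
#' @param dropout_main dropout on the concatenated pair representation.
#' @param dropout_node dropout on raw input features.
#' @param dropout_feat dropout on hidden states between layers.
#' @param epochs maximum training epochs (full-batch).
#' @param patience early-stop patience on the training-loss plateau;
#'   `Inf` disables early stopping.
#' @param seed base RNG seed controlling initialisation, Gumbel draws
#'   and dropout.
#' @param gate_gamma gating temperature in `sigmoid((W - tau)/gamma)`.
#' @param gumbel_tau Gumbel-Softmax temperature for order sampling.
#' @param clip,eps stabilisation constants for high-order moments.
#' @param attention cross-order scoring: `"additive"` or `"linear"`.
#' @param act nonlinearity of the node update (`"elu"`, `"relu"`,
#'   `"identity"`).
#' @param threshold classification threshold for accuracy/precision/F1.
#' @param embed_dim node2vec embedding dimensionality.
#' @param n2v_p,n2v_q,n2v_walk_length,n2v_walks,n2v_window,n2v_iters
#'   node2vec walk and skip-gram parameters.
#' @param cv_k number of cross-validation folds.
#' @param strict_holdout also remove test-fold edges from the
#'   message-passing adjacency (off by default: the graph and GIP
#'   similarities are built once from all known associations, only the
#'   labels are held out).
#' @param gip_per_fold recompute GIP similarity from training-fold
#'   associations inside each fold instead of once globally.
#' @param scale_weights also multiply the sampled order weight `W_k` into
#'   the effective weight (variant; default uses gate x mask only).
#' @return a list of class `"magmda_config"`.
#' @export
magmda_config <- function(hidden_dim = 64, n_layers = 2, m_max = 10, top_k = 5,
                          lr = 5e-5, weight_decay = 1e-3,
                          dropout_main = 0.3, dropout_node = 0.2, dropout_feat = 0.2,
                          epochs = 400, patience = 50, seed = 1234,
                          gate_gamma = 0.1, gumbel_tau = 1.0,
                          clip = 10, eps = 1e-6,
                          attention = c("additive", "linear"),
                          act = c("elu", "relu", "identity"),
                          threshold = 0.5, embed_dim = 64,
                          n2v_p = 1, n2v_q = 1, n2v_walk_length = 80,
                          n2v_walks = 10, n2v_window = 5, n2v_iters = 5,
                          cv_k = 5, strict_holdout = FALSE, gip_per_fold = FALSE,
                          scale_weights = FALSE) {
  cfg <- list(hidden_dim = hidden_dim, n_layers = n_layers, m_max = m_max,
              top_k = top_k, lr = lr, weight_decay = weight_decay,
              dropout_main = dropout_main, dropout_node = dropout_node,
              dropout_feat = dropout_feat, epochs = epochs, patience = patience,
              seed = seed, gate_gamma = gate_gamma, gumbel_tau = gumbel_tau,
              clip = clip, eps = eps, attention = match.arg(attention),
              act = match.arg(act), threshold = threshold, embed_dim = embed_dim,
              n2v_p = n2v_p, n2v_q = n2v_q, n2v_walk_length = n2v_walk_length,
              n2v_walks = n2v_walks, n2v_window = n2v_window, n2v_iters = n2v_iters,
              cv_k = cv_k, strict_holdout = strict_holdout,
              gip_per_fold = gip_per_fold, scale_weights = scale_weights)
  stopifnot(cfg$hidden_dim > 0, cfg$n_layers > 0, cfg$m_max >= 1, cfg$top_k >= 1,
            cfg$lr > 0, cfg$gate_gamma > 0, cfg$gumbel_tau > 0)
  class(cfg) <- "magmda_config"
  cfg
}

# ---- parameters ------------------------------------------------------

init_params <- function(raw_dim, cfg) {
  h <- cfg$hidden_dim
  layer_init <- function() {
    list(alpha = numeric(cfg$m_max),
         W1 = matrix(0, h, 16), b1 = numeric(16), w2 = numeric(16), b2 = 0,
         Wz = lapply(seq_len(cfg$m_max), function(k) glorot(h, h)),
         bz = lapply(seq_len(cfg$m_max), function(k) numeric(h)),
         a = stats::runif(h, -sqrt(6 / (h + 1)), sqrt(6 / (h + 1))))
  }
  list(win = glorot(raw_dim, h), bin = numeric(h),
       layers = lapply(seq_len(cfg$n_layers), function(l) layer_init()),
       w = numeric(2 * h), b = 0)
}

tree_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

adam_step <- function(params, grads, state, cfg, t) {
  b1 <- 0.9; b2 <- 0.999; ae <- 1e-8
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- vector("list", length(p)); out_m <- out_p; out_v <- out_p
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      names(out_p) <- names(p); names(out_m) <- names(p); names(out_v) <- names(p)
      return(list(p = out_p, m = out_m, v = out_v))
    }
    g <- g + cfg$weight_decay * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(p = p - cfg$lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + ae),
         m = m, v = v)
  }
  upd(params, grads, state$m, state$v)
}

# ---- forward / backward ----------------------------------------------

dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

model_forward <- function(feats, adj, params, cfg, train = FALSE) {
  f_in <- feats
  mask_node <- NULL
  if (train && cfg$dropout_node > 0) {
    mask_node <- dropout_mask(nrow(feats), ncol(feats), cfg$dropout_node)
    f_in <- f_in * mask_node
  }
  h <- f_in %*% params$win
  h <- sweep(h, 2L, params$bin, `+`)
  caches <- vector("list", cfg$n_layers)
  masks_feat <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lf <- layer_forward(h, adj, params$layers[[l]], cfg, train = train)
    h <- lf$h_next
    if (train && cfg$dropout_feat > 0) {
      masks_feat[[l]] <- dropout_mask(nrow(h), ncol(h), cfg$dropout_feat)
      h <- h * masks_feat[[l]]
    }
    caches[[l]] <- lf$cache
  }
  list(h = h, caches = caches, f_in = f_in, mask_node = mask_node,
       masks_feat = masks_feat)
}

model_backward <- function(dh, fw, params, cfg) {
  grads_layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    if (!is.null(fw$masks_feat[[l]])) dh <- dh * fw$masks_feat[[l]]
    lb <- layer_backward(dh, fw$caches[[l]], params$layers[[l]], cfg)
    grads_layers[[l]] <- lb$grads
    dh <- lb$dh
  }
  dwin <- crossprod(fw$f_in, dh)
  dbin <- colSums(dh)
  list(win = dwin, bin = dbin, layers = grads_layers)
}

#' Score disease-miRNA pairs from node embeddings
#'
#' Concatenates the disease and miRNA embeddings of each pair and applies
#' the linear pair scorer with a sigmoid:
#' `yhat = sigmoid(w' [h_d; h_m] + b)`.
#'
#' @param h_d disease embedding matrix (`n_D x hidden`).
#' @param h_m miRNA embedding matrix (`n_M x hidden`).
#' @param pairs 2-column integer matrix of (disease, miRNA) indices.
#' @param scorer list with weight vector `w` (length `2 * hidden`) and
#'   scalar bias `b`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
score_pairs <- function(h_d, h_m, pairs, scorer) {
  if (any(pairs[, 1L] < 1 | pairs[, 1L] > nrow(h_d)) ||
      any(pairs[, 2L] < 1 | pairs[, 2L] > nrow(h_m)))
    stop("pair index out of range")
  u <- cbind(h_d[pairs[, 1L], , drop = FALSE], h_m[pairs[, 2L], , drop = FALSE])
  sigmoid(drop(u %*% scorer$w) + scorer$b)
}

#' Mean binary cross-entropy loss
#'
#' `-(1/N) sum(y log(yhat) + (1 - y) log(1 - yhat))`, with predictions
#' clamped to `[1e-7, 1 - 1e-7]` so the loss stays finite.
#'
#' @param yhat predicted probabilities.
#' @param y 0/1 labels.
#' @return scalar loss.
#' @export
bce_loss <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("prediction/label length mismatch")
  p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- core trainer ----------------------------------------------------

# Full-batch Adam training of the model on the given (pairs, labels)
# sample set. All randomness (init, Gumbel draws, dropout) is driven by
# `seed`. Returns trained parameters and the loss history.
fit_core <- function(feats, adj, n_diseases, pairs, labels, cfg, seed,
                     verbose = FALSE) {
  nd <- n_diseases
  local_seed(seed, {
    params <- init_params(ncol(feats), cfg)
    state <- list(m = tree_map(params, function(x) x * 0),
                  v = tree_map(params, function(x) x * 0))
    n_samp <- nrow(pairs)
    loss_hist <- numeric(0)
    best <- Inf; stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      fw <- model_forward(feats, adj, params, cfg, train = TRUE)
      h_d <- fw$h[seq_len(nd), , drop = FALSE]
      h_m <- fw$h[-seq_len(nd), , drop = FALSE]
      u <- cbind(h_d[pairs[, 1L], , drop = FALSE], h_m[pairs[, 2L], , drop = FALSE])
      mask_u <- if (cfg$dropout_main > 0) dropout_mask(nrow(u), ncol(u), cfg$dropout_main) else NULL
      if (!is.null(mask_u)) u <- u * mask_u
      logit <- drop(u %*% params$w) + params$b
      yhat <- sigmoid(logit)
      loss <- bce_loss(yhat, labels)
      if (!is.finite(loss))
        stop("training diverged at epoch ", epoch, " (non-finite loss); ",
             "last finite loss ",
             if (length(loss_hist)) signif(utils::tail(loss_hist, 1), 6) else NA)
      loss_hist <- c(loss_hist, loss)

      dlogit <- (yhat - labels) / n_samp
      dw <- drop(crossprod(u, dlogit))
      db <- sum(dlogit)
      du <- outer(dlogit, params$w)
      if (!is.null(mask_u)) du <- du * mask_u
      hidden <- cfg$hidden_dim
      dh <- matrix(0, nrow(feats), hidden)
      dh_d <- rowsum(du[, seq_len(hidden), drop = FALSE], pairs[, 1L], reorder = FALSE)
      dh[as.integer(rownames(dh_d)), ] <- dh_d
      dh_m <- rowsum(du[, hidden + seq_len(hidden), drop = FALSE], pairs[, 2L], reorder = FALSE)
      dh[nd + as.integer(rownames(dh_m)), ] <-
        dh[nd + as.integer(rownames(dh_m)), , drop = FALSE] + dh_m
      grads <- model_backward(dh, fw, params, cfg)
      grads$w <- dw; grads$b <- db

      res <- adam_step(params, grads, state, cfg, epoch)
      params <- res$p; state <- list(m = res$m, v = res$v)

      if (loss < best - 1e-5) { best <- loss; stall <- 0L } else stall <- stall + 1L
      if (stall >= cfg$patience) break
      if (verbose && epoch %% 50 == 0)
        message(sprintf("epoch %d  loss %.5f", epoch, loss))
    }
    list(params = params, loss = loss_hist)
  })
}

# Deterministic inference pass + diagnostics snapshot per layer.
infer_embeddings <- function(feats, adj, params, cfg) {
  fw <- model_forward(feats, adj, params, cfg, train = FALSE)
  diag_layers <- lapply(seq_len(cfg$n_layers), function(l) {
    ca <- fw$caches[[l]]
    att <- ca$attn
    list(layer = l, mask = ca$mask, w = ca$w, gates = ca$g, tau = ca$tau,
         attn_mean = colMeans(att),
         attn_q = apply(att, 2L, stats::quantile,
                        probs = c(0.25, 0.5, 0.75), names = FALSE))
  })
  list(h = fw$h, diagnostics = diag_layers)
}
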