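test_that("order-weight sampling is a softmax at inference and Gumbel-perturbed in training", {
  expect_equal(sample_order_weights(rep(0, 10), "infer"), rep(0.1, 10))
  expect_equal(sample_order_weights(c(log(2), 0), "infer"), c(2 / 3, 1 / 3))
  w <- sample_order_weights(rnorm(6), "train", gumbel_temperature = 1, seed = 4)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
  # temperature -> 0 with a fixed noise realisation approaches one-hot
  logits <- c(0.5, -0.2, 0.1, 0.4)
  w_hot <- sample_order_weights(logits, "train", gumbel_temperature = 1e-3, seed = 9)
  w_soft <- sample_order_weights(logits, "train", gumbel_temperature = 1.0, seed = 9)
  expect_gt(max(w_hot), 1 - 1e-6)
  expect_equal(which.max(w_hot), which.max(w_soft))
  expect_lt(max(w_soft), 0.9)
  expect_error(sample_order_weights(logits, "train", gumbel_temperature = 0),
               "positive")
})

test_that("dynamic threshold starts at half its scale and is permutation invariant", {
  h <- matrix(rnorm(40), 10, 4)
  net <- init_threshold_net(4, init = "zero")
  expect_equal(dynamic_threshold(h, net, tau_scale = 0.2), 0.1)
  net2 <- local_seed_test(2, init_threshold_net(4, init = "glorot"))
  net2$w2 <- rnorm(16, 0, 0.5)
  tau <- dynamic_threshold(h, net2, tau_scale = 0.2)
  expect_gt(tau, 0); expect_lt(tau, 0.2)
  expect_equal(dynamic_threshold(h[sample.int(10), ], net2, tau_scale = 0.2), tau)
})

test_that("gating follows the logistic comparison with the threshold", {
  expect_equal(gate_orders(0.3, 0.3, 0.1), 0.5)
  expect_equal(gate_orders(0.4, 0.3, 0.1), 1 / (1 + exp(-1)), tolerance = 1e-9)
  # hard-threshold limit
  g <- gate_orders(c(0.31, 0.29), 0.3, 1e-6)
  expect_equal(g, c(1, 0), tolerance = 1e-9)
  expect_error(gate_orders(0.5, 0.3, 0), "positive")
})

test_that("Top-K retention keeps exactly min(K, M) orders with low-order tie-breaks", {
  w <- c(0.05, 0.2, 0.1, 0.25, 0.08, 0.02, 0.12, 0.06, 0.07, 0.05)
  g <- rep(0.9, 10)
  ew <- effective_weights(g, w, k = 5)
  expect_equal(sum(ew$mask), 5)
  expect_equal(sum(ew$w_eff != 0), 5)
  # K >= M keeps everything, effective weights equal the gates
  ew_all <- effective_weights(g, w, k = 12)
  expect_equal(ew_all$mask, rep(1, 10))
  expect_equal(ew_all$w_eff, g)
  # tie at 0.3 broken toward the lower order
  ew_tie <- effective_weights(c(0.7, 0.7, 0.7), c(0.3, 0.3, 0.4), k = 2)
  expect_equal(which(ew_tie$mask == 1), c(1L, 3L))
})

test_that("cross-order attention normalises over retained orders only", {
  n <- 6; hidden <- 4; m_max <- 4
  moments <- lapply(1:m_max, function(k) matrix(0, n, hidden))
  proj <- list(W = lapply(1:m_max, function(k) diag(hidden)),
               b = lapply(1:m_max, function(k) numeric(hidden)))
  attn_vec <- rep(0.3, hidden)
  # all four retained with identical (zero) embeddings -> equal scores -> 0.25
  ca <- cross_order_attention(moments, w_eff = rep(0.5, 4), proj, attn_vec)
  expect_equal(unname(ca$attn), matrix(0.25, n, m_max))
  # mask one order out: equal scores on the rest -> (0.5, 0.5, 0)
  ca2 <- cross_order_attention(moments[1:3], w_eff = c(0.5, 0.5, 0),
                               list(W = proj$W[1:3], b = proj$b[1:3]), attn_vec)
  expect_equal(unname(ca2$attn), cbind(rep(0.5, n), rep(0.5, n), rep(0, n)))
  expect_null(ca2$z[[3]])
  # random inputs: rows sum to 1 within 1e-6, masked entries exactly 0
  res <- local_seed_test(5, {
    mom <- lapply(1:m_max, function(k) matrix(rnorm(n * hidden), n, hidden))
    pr <- list(W = lapply(1:m_max, function(k) matrix(rnorm(hidden^2), hidden)),
               b = lapply(1:m_max, function(k) rnorm(hidden)))
    list(mom = mom, pr = pr, av = rnorm(hidden))
  })
  ca3 <- cross_order_attention(res$mom, w_eff = c(0.4, 0, 0.8, 0.1),
                               res$pr, res$av, type = "linear")
  expect_equal(rowSums(ca3$attn), rep(1, n), tolerance = 1e-6)
  expect_true(all(ca3$attn[, 2] == 0))
})

test_that("node update is residual with the chosen nonlinearity", {
  h <- matrix(c(-2, 0.5, 1, -0.3), 2, 2)
  zs <- list(matrix(0, 2, 2))
  attn <- matrix(1, 2, 1)
  # all-zero candidates: pure residual through the activation
  expect_equal(update_nodes(h, zs, attn, act = "elu"),
               ifelse(h > 0, h, exp(h) - 1))
  # zero state, one retained order with constant embedding c
  z1 <- list(matrix(2, 2, 2))
  expect_equal(update_nodes(matrix(0, 2, 2), z1, attn, act = "relu"),
               matrix(2, 2, 2))
  expect_equal(dim(update_nodes(h, zs, attn)), dim(h))
  expect_error(update_nodes(h, list(matrix(0, 2, 3)), attn), "width")
})

test_that("the fused layer equals the composition of its exported operations", {
  at <- random_assoc(5, 5, seed = 3)
  adj <- normalize_adjacency(build_graph(at))
  cfg <- magmda_config(hidden_dim = 6, m_max = 4, top_k = 3)
  res <- local_seed_test(21, {
    lp <- magmda:::init_params(6, cfg)$layers[[1]]
    lp$w2 <- rnorm(16, 0, 0.3)
    lp$alpha <- rnorm(4, 0, 0.5)
    list(lp = lp, h = matrix(rnorm(60), 10, 6))
  })
  lf <- magmda:::layer_forward(res$h, adj, res$lp, cfg, train = FALSE)
  w <- sample_order_weights(res$lp$alpha, "infer")
  tau <- dynamic_threshold(res$h, list(W1 = res$lp$W1, b1 = res$lp$b1,
                                       w2 = res$lp$w2, b2 = res$lp$b2),
                           tau_scale = 2 / cfg$m_max)
  g <- gate_orders(w, tau, cfg$gate_gamma)
  ew <- effective_weights(g, w, cfg$top_k)
  mom <- stabilize_moments(res$h, adj, cfg$m_max, orders = which(ew$mask == 1))
  ca <- cross_order_attention(mom, ew$w_eff, list(W = res$lp$Wz, b = res$lp$bz),
                              res$lp$a, "additive")
  hn <- update_nodes(res$h, ca$z, ca$attn, cfg$act)
  expect_equal(lf$h_next, hn, tolerance = 1e-12)
})

test_that("layer output is permutation equivariant", {
  at <- random_assoc(5, 6, seed = 13)
  adj <- as.matrix(normalize_adjacency(build_graph(at)))
  cfg <- magmda_config(hidden_dim = 5, m_max = 4, top_k = 3)
  res <- local_seed_test(31, {
    lp <- magmda:::init_params(5, cfg)$layers[[1]]
    lp$alpha <- rnorm(4, 0, 0.4)
    lp$w2 <- rnorm(16, 0, 0.3)
    list(lp = lp, h = matrix(rnorm(55), 11, 5), perm = sample.int(11))
  })
  out <- magmda:::layer_forward(res$h, adj, res$lp, cfg, train = FALSE)$h_next
  out_p <- magmda:::layer_forward(res$h[res$perm, ], adj[res$perm, res$perm],
                                  res$lp, cfg, train = FALSE)$h_next
  expect_equal(out_p, out[res$perm, ], tolerance = 1e-10)
})
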