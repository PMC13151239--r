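test_that("pair scoring applies the logistic linear form", {
  h_d <- matrix(rnorm(12), 3, 4)
  h_m <- matrix(rnorm(16), 4, 4)
  pairs <- cbind(c(1, 2, 3), c(1, 4, 2))
  s0 <- score_pairs(h_d, h_m, pairs, list(w = numeric(8), b = 0))
  expect_equal(s0, rep(0.5, 3))
  s1 <- score_pairs(h_d, h_m, pairs, list(w = numeric(8), b = log(3)))
  expect_equal(s1, rep(0.75, 3), tolerance = 1e-12)
  sr <- score_pairs(h_d, h_m, pairs, list(w = rnorm(8, 0, 5), b = 1))
  expect_true(all(sr > 0 & sr < 1))
  expect_error(score_pairs(h_d, h_m, cbind(4, 1), list(w = numeric(8), b = 0)),
               "out of range")
})

test_that("binary cross-entropy matches hand evaluation and stays finite", {
  expect_equal(bce_loss(rep(0.5, 4), c(1, 0, 1, 0)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -log(0.9), tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("metrics reproduce the confusion-matrix formulas and ranking areas", {
  # TP=3, TN=4, FP=1, FN=2 at threshold 0.5
  labels <- c(rep(1, 5), rep(0, 5))
  scores <- c(.9, .8, .7, .2, .1, .6, .4, .3, .2, .1)
  m <- compute_metrics(scores, labels)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 6 / 9, tolerance = 1e-9)

  # perfectly separated scores
  mp <- compute_metrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))
  expect_equal(mp$auc, 1)
  expect_equal(mp$aupr, 1)

  # label-independent scores: AUC near 0.5 at large n
  res <- local_seed_test(2, list(s = runif(1e4), y = rbinom(1e4, 1, 0.5)))
  expect_equal(compute_metrics(res$s, res$y)$auc, 0.5, tolerance = 0.02)

  expect_error(compute_metrics(c(.1, .2), c(1, 1)), "one class")
})

test_that("rank-based AUC equals the brute-force all-pairs oracle", {
  for (seed in 1:6) {
    res <- local_seed_test(seed, {
      n <- sample(10:200, 1)
      s <- round(runif(n), 2)           # rounding forces ties
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0) y[1] <- 1
      if (sum(y) == n) y[1] <- 0
      list(s = s, y = y)
    })
    expect_equal(compute_metrics(res$s, res$y)$auc, auc_oracle(res$s, res$y))
  }
})

test_that("fold aggregation reports the plain mean and SD of fold metrics", {
  fm <- list(list(auc = .9, aupr = .8), list(auc = .7, aupr = .6),
             list(auc = .8, aupr = .7))
  ag <- magmda:::aggregate_metrics(fm)
  expect_equal(ag$mean[ag$metric == "auc"], mean(c(.9, .7, .8)))
  expect_equal(ag$sd[ag$metric == "aupr"], sd(c(.8, .6, .7)))
})

test_that("model forward has the contracted shapes and inference is deterministic", {
  at <- random_assoc(3, 4, seed = 1)
  cfg <- magmda_config(hidden_dim = 8, m_max = 4, top_k = 2, embed_dim = 6)
  adj <- normalize_adjacency(build_graph(at))
  feats <- local_seed_test(3, matrix(rnorm(7 * 10), 7, 10))
  params <- local_seed_test(4, magmda:::init_params(10, cfg))
  f1 <- magmda:::model_forward(feats, adj, params, cfg, train = FALSE)
  expect_equal(dim(f1$h), c(7L, 8L))
  expect_equal(dim(f1$h[1:3, ]), c(3L, 8L))   # disease block
  expect_equal(dim(f1$h[4:7, ]), c(4L, 8L))   # miRNA block
  f2 <- magmda:::model_forward(feats, adj, params, cfg, train = FALSE)
  expect_identical(f1$h, f2$h)
  # training mode applies dropout and Gumbel noise: outputs differ run to run
  t1 <- local_seed_test(5, magmda:::model_forward(feats, adj, params, cfg, train = TRUE))
  t2 <- local_seed_test(6, magmda:::model_forward(feats, adj, params, cfg, train = TRUE))
  expect_false(identical(t1$h, t2$h))
  expect_false(is.null(t1$mask_node))
  expect_true(is.null(f1$mask_node))
})

test_that("analytic gradients match finite differences, including the order logits", {
  at <- random_assoc(4, 5, seed = 2)
  adj <- normalize_adjacency(build_graph(at))
  cfg <- magmda_config(hidden_dim = 5, n_layers = 2, m_max = 4, top_k = 3,
                       dropout_main = 0, dropout_node = 0, dropout_feat = 0)
  res <- local_seed_test(42, {
    params <- magmda:::init_params(7, cfg)
    params$layers[[1]]$alpha <- rnorm(4, 0, 0.5)
    params$layers[[2]]$alpha <- rnorm(4, 0, 0.5)
    params$layers[[1]]$w2 <- rnorm(16, 0, 0.3)
    params$w <- rnorm(10, 0, 0.3)
    list(params = params, feats = matrix(rnorm(9 * 7), 9, 7))
  })
  samp <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 5))
  y <- c(1, 0, 1, 0)
  loss_of <- function(p) {
    fw <- magmda:::model_forward(res$feats, adj, p, cfg, train = FALSE)
    yhat <- score_pairs(fw$h[1:4, ], fw$h[5:9, ], samp, list(w = p$w, b = p$b))
    bce_loss(yhat, y)
  }
  grads <- local({
    p <- res$params
    fw <- magmda:::model_forward(res$feats, adj, p, cfg, train = FALSE)
    h_d <- fw$h[1:4, , drop = FALSE]; h_m <- fw$h[5:9, , drop = FALSE]
    u <- cbind(h_d[samp[, 1], ], h_m[samp[, 2], ])
    yhat <- 1 / (1 + exp(-(drop(u %*% p$w) + p$b)))
    dlogit <- (yhat - y) / length(y)
    du <- outer(dlogit, p$w)
    dh <- matrix(0, 9, 5)
    for (r in 1:4) {
      dh[samp[r, 1], ] <- dh[samp[r, 1], ] + du[r, 1:5]
      dh[4 + samp[r, 2], ] <- dh[4 + samp[r, 2], ] + du[r, 6:10]
    }
    g <- magmda:::model_backward(dh, fw, p, cfg)
    g$w <- drop(crossprod(u, dlogit)); g$b <- sum(dlogit)
    g
  })
  num <- function(setter) {
    eps <- 1e-4   # large enough to dominate double-precision roundoff in the loss
    (loss_of(setter(res$params, eps)) - loss_of(setter(res$params, -eps))) / (2 * eps)
  }
  expect_close <- function(a, b, rel = 2e-2) {
    expect_lt(abs(a - b) / max(1e-6, abs(a), abs(b)), rel)
  }
  bump_top <- function(name, idx) function(p, e) {
    p[[name]][idx] <- p[[name]][idx] + e
    p
  }
  bump_layer <- function(l, name, idx) function(p, e) {
    p$layers[[l]][[name]][idx] <- p$layers[[l]][[name]][idx] + e
    p
  }
  expect_close(grads$win[2, 3], num(bump_top("win", cbind(2, 3))))
  expect_close(grads$layers[[1]]$alpha[2], num(bump_layer(1, "alpha", 2)))
  expect_close(grads$layers[[2]]$alpha[1], num(bump_layer(2, "alpha", 1)))
  # gradient reaches the order logits: nonzero for at least one retained order
  expect_gt(max(abs(grads$layers[[1]]$alpha)), 0)
  expect_close(grads$layers[[1]]$a[3], num(bump_layer(1, "a", 3)))
  expect_close(grads$w[4], num(bump_top("w", 4)), rel = 1e-4)
  expect_close(grads$b, num(bump_top("b", 1)), rel = 1e-4)
})

test_that("training decreases the loss, stays finite and is seed-reproducible", {
  synth <- synthetic_mda(n_diseases = 30, n_mirnas = 30, n_blocks = 2,
                         p_in = 0.5, p_out = 0.05, seed = 1234)
  cfg <- fast_config(epochs = 40, seed = 1234)
  inputs <- magmda:::prepare_inputs(synth$assoc, synth$dis_sim, synth$mir_sim, cfg)
  negs <- sample_negatives(synth$assoc, nrow(synth$assoc$pairs), seed = 3)
  pairs <- rbind(synth$assoc$pairs, negs)
  y <- c(rep(1, nrow(synth$assoc$pairs)), rep(0, nrow(negs)))
  fit <- magmda:::fit_core(inputs$feats, inputs$adj, 30, pairs, y, cfg, seed = 1234)
  expect_true(all(is.finite(fit$loss)))
  expect_lt(min(fit$loss[2:10]), fit$loss[1])            # early decrease
  expect_lt(mean(utils::tail(fit$loss, 10)), mean(fit$loss[1:10]))
  fit2 <- magmda:::fit_core(inputs$feats, inputs$adj, 30, pairs, y, cfg, seed = 1234)
  expect_identical(fit$loss, fit2$loss)
  expect_equal(fit$params, fit2$params)
})

test_that("the fitted model object supports the standard methods", {
  synth <- synthetic_mda(n_diseases = 15, n_mirnas = 20, n_blocks = 2,
                         p_in = 0.6, p_out = 0.05, seed = 3)
  cfg <- fast_config(epochs = 8, seed = 11)
  fit <- magmda(synth$assoc, synth$dis_sim, synth$mir_sim, cfg)
  expect_s3_class(fit, "magmda")
  expect_output(print(fit), "association model")
  co <- coef(fit)
  expect_equal(dim(co$order_weights), c(2L, 10L))
  expect_equal(rowSums(co$order_weights), c(layer1 = 1, layer2 = 1))

  pr <- predict(fit, data.frame(disease = "d001", mirna = c("m001", "m002")))
  expect_true(all(pr$score > 0 & pr$score < 1))
  expect_error(predict(fit, data.frame(disease = "nope", mirna = "m001")),
               "unknown disease")

  rk <- rank_candidates(fit, "d001", top_n = 50)
  expect_equal(nrow(rk), 20L)                   # top_n >= n_mirnas: full ranking
  expect_true(all(diff(rk$score) <= 0))         # non-increasing
  rk5 <- rank_candidates(fit, "d001", top_n = 5)
  expect_equal(nrow(rk5), 5L)
  expect_error(rank_candidates(fit, "no-such-disease"), "unknown disease")
})

test_that("cross-validation holds out each fold and reports per-fold metrics", {
  synth <- synthetic_mda(n_diseases = 20, n_mirnas = 20, n_blocks = 2,
                         p_in = 0.6, p_out = 0.05, seed = 21)
  cfg <- fast_config(epochs = 8, seed = 7, cv_k = 3)
  cv <- magmda_cv(synth$assoc, synth$dis_sim, synth$mir_sim, cfg)
  expect_s3_class(cv, "magmda_cv")
  expect_length(cv$folds, 3L)
  sm <- summary(cv)
  expect_equal(nrow(sm$per_fold), 3L)
  expect_true(all(unlist(sm$per_fold[, -1]) >= 0 & unlist(sm$per_fold[, -1]) <= 1))
  # each fold's predictions cover exactly its held-out samples
  for (f in 1:3) {
    n_te <- sum(cv$partition$fold_pos == f) + sum(cv$partition$fold_neg == f)
    expect_equal(nrow(cv$folds[[f]]$predictions), n_te)
  }
  # diagnostics: one record per (fold, layer)
  expect_length(cv$diagnostics, 3L * cfg$n_layers)
  out <- withr::local_tempdir()
  write_cv_results(cv, out)
  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "predictions.tsv")))
})
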