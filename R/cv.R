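# Shared pipeline front end: similarity integration, graph, embeddings,
# node features. `dis_sim` / `mir_sim` may be NULL, in which case the
# GIP kernel alone provides that side's similarity.
prepare_inputs <- function(assoc, dis_sim = NULL, mir_sim = NULL, cfg) {
  sims <- integrated_sims(assoc, dis_sim, mir_sim)
  graph <- build_graph(assoc)
  topo <- node2vec_embed(graph, dim = cfg$embed_dim, p = cfg$n2v_p, q = cfg$n2v_q,
                         walk_length = cfg$n2v_walk_length, n_walks = cfg$n2v_walks,
                         window = cfg$n2v_window, iters = cfg$n2v_iters,
                         seed = derive_seed(cfg$seed, 11L))
  feats <- build_node_features(sims$i_d, sims$i_m, topo)
  list(graph = graph, adj = normalize_adjacency(graph),
       feats = feats, i_d = sims$i_d, i_m = sims$i_m, topo = topo,
       dis_sim = dis_sim, mir_sim = mir_sim)
}

# GIP kernels from `gip_source` (defaults to `assoc`) integrated with the
# optional primary similarities of `assoc`'s universe.
integrated_sims <- function(assoc, dis_sim, mir_sim, gip_source = assoc) {
  gip_d <- gip_kernel(to_profile_matrix(gip_source, "disease"))
  gip_m <- gip_kernel(to_profile_matrix(gip_source, "mirna"))
  i_d <- if (is.null(dis_sim)) gip_d else {
    check_sim_labels(dis_sim, assoc$disease_ids, "disease")
    integrate_similarity(dis_sim, gip_d)
  }
  i_m <- if (is.null(mir_sim)) gip_m else {
    check_sim_labels(mir_sim, assoc$mirna_ids, "miRNA")
    integrate_similarity(mir_sim, gip_m)
  }
  list(i_d = i_d, i_m = i_m)
}

check_sim_labels <- function(sim, ids, what) {
  if (!identical(rownames(sim), ids))
    stop(what, " similarity labels do not match the association table ",
         "(same identifiers in the same order required; use read_similarity(..., ",
         "expected_labels = ...) to reorder)")
}

# small deterministic seed derivation, kept below .Machine$integer.max
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 131L + salt) %% 2147483L + salt)
}

#' Train and evaluate a single cross-validation fold
#'
#' Trains a fresh model on the training folds' positive and negative
#' samples (test-fold samples contribute no labels) and evaluates on the
#' held-out fold. The message-passing adjacency keeps all association
#' edges by default (`strict_holdout = FALSE` in the configuration);
#' strict mode removes the test-fold edges before normalisation.
#'
#' @param partition a [make_folds()] sample partition.
#' @param fold fold index in `1..k` to hold out.
#' @param inputs prepared pipeline inputs (internal; produced by
#'   [magmda_cv()]).
#' @param cfg a [magmda_config()].
#' @param assoc the [association_table()].
#' @return list of class `"magmda_fold"`: `fold`, `metrics`,
#'   `predictions` (data.frame), `diagnostics`, `loss`.
#' @keywords internal
train_fold <- function(partition, fold, inputs, cfg, assoc) {
  if (fold < 1 || fold > partition$k) stop("invalid fold index")
  tr_pos <- partition$positives[partition$fold_pos != fold, , drop = FALSE]
  tr_neg <- partition$negatives[partition$fold_neg != fold, , drop = FALSE]
  te_pos <- partition$positives[partition$fold_pos == fold, , drop = FALSE]
  te_neg <- partition$negatives[partition$fold_neg == fold, , drop = FALSE]
  train_pairs <- rbind(tr_pos, tr_neg)
  train_y <- c(rep(1, nrow(tr_pos)), rep(0, nrow(tr_neg)))
  test_pairs <- rbind(te_pos, te_neg)
  test_y <- c(rep(1, nrow(te_pos)), rep(0, nrow(te_neg)))

  adj <- inputs$adj
  feats <- inputs$feats
  if (cfg$strict_holdout)
    adj <- normalize_adjacency(inputs$graph, drop_pairs = te_pos)
  if (cfg$gip_per_fold) {
    tr_assoc <- assoc
    tr_assoc$pairs <- tr_pos
    sims <- integrated_sims(assoc, inputs$dis_sim, inputs$mir_sim,
                            gip_source = tr_assoc)
    feats <- build_node_features(sims$i_d, sims$i_m, inputs$topo)
  }

  nd <- inputs$graph$n_diseases
  fit <- fit_core(feats, adj, nd, train_pairs, train_y, cfg,
                  seed = derive_seed(cfg$seed, fold))
  inf <- infer_embeddings(feats, adj, fit$params, cfg)
  h_d <- inf$h[seq_len(nd), , drop = FALSE]
  h_m <- inf$h[-seq_len(nd), , drop = FALSE]
  scorer <- list(w = fit$params$w, b = fit$params$b)
  yhat <- score_pairs(h_d, h_m, test_pairs, scorer)
  metrics <- compute_metrics(yhat, test_y, threshold = cfg$threshold)
  diagnostics <- lapply(inf$diagnostics, function(d) { d$fold <- fold; d })
  structure(list(fold = fold, metrics = metrics,
                 predictions = data.frame(
                   disease = assoc$disease_ids[test_pairs[, 1L]],
                   mirna = assoc$mirna_ids[test_pairs[, 2L]],
                   score = yhat, label = test_y, fold = fold),
                 diagnostics = diagnostics, loss = fit$loss),
            class = "magmda_fold")
}

#' Five-fold cross-validated training and evaluation
#'
#' Runs the full pipeline on an association table: GIP kernels are
#' computed once from all associations and integrated with the provided
#' semantic/functional similarities, node2vec embeds the bidirected
#' graph, negatives are sampled once globally (one per positive), and
#' the samples are partitioned at the association level into `cfg$cv_k`
#' folds. Each fold trains a fresh model on the remaining folds and is
#' evaluated on the held-out fold; fold metrics are reported with their
#' mean and standard deviation.
#'
#' @param assoc an [association_table()] (or path to a TSV association
#'   list).
#' @param dis_sim,mir_sim optional disease semantic / miRNA functional
#'   [similarity_matrix()] objects with labels matching `assoc`; when
#'   `NULL` the GIP kernel alone is used for that side.
#' @param config a [magmda_config()].
#' @param folds fold indices to train/evaluate (default all
#'   `1..config$cv_k`); the partition is always formed over all folds so
#'   a subset run uses the same splits.
#' @return object of class `"magmda_cv"`: `folds` (list of fold
#'   results), `summary` (mean/sd data.frame), `partition`, `config`,
#'   `diagnostics` (flat list of per-fold, per-layer selection records).
#' @export
magmda_cv <- function(assoc, dis_sim = NULL, mir_sim = NULL,
                      config = magmda_config(), folds = NULL) {
  if (is.character(assoc)) assoc <- read_associations(assoc)
  stopifnot(inherits(assoc, "assoc_table"))
  cfg <- config
  inputs <- prepare_inputs(assoc, dis_sim, mir_sim, cfg)
  negatives <- sample_negatives(assoc, nrow(assoc$pairs),
                                seed = derive_seed(cfg$seed, 29L))
  partition <- make_folds(assoc$pairs, negatives, k = cfg$cv_k,
                          seed = derive_seed(cfg$seed, 31L))
  if (is.null(folds)) folds <- seq_len(cfg$cv_k)
  folds <- lapply(folds, function(f)
    train_fold(partition, f, inputs, cfg, assoc))
  diagnostics <- do.call(c, lapply(folds, `[[`, "diagnostics"))
  structure(list(folds = folds,
                 summary = aggregate_metrics(lapply(folds, `[[`, "metrics")),
                 partition = partition, config = cfg,
                 diagnostics = diagnostics, assoc = assoc),
            class = "magmda_cv")
}

#' @export
#' @method print magmda_cv
print.magmda_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of the adaptive moment association model\n",
              x$config$cv_k))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' @export
#' @method summary magmda_cv
summary.magmda_cv <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(object$folds, function(f)
    data.frame(fold = f$fold, as.data.frame(f$metrics))))
  list(summary = object$summary, per_fold = per_fold)
}

#' Export per-fold metrics and predictions of a cross-validation run
#'
#' @param x a [magmda_cv()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `metrics.tsv` and `predictions.tsv`.
#' @export
write_cv_results <- function(x, dir) {
  stopifnot(inherits(x, "magmda_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_fold <- summary(x)$per_fold
  utils::write.table(per_fold, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  preds <- do.call(rbind, lapply(x$folds, `[[`, "predictions"))
  utils::write.table(preds, file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
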