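#' Fit the adaptive multi-order moment association model
#'
#' The main fitting function. Builds the full pipeline from an
#' association table: Gaussian interaction profile (GIP) kernels are
#' integrated with the supplied disease semantic and miRNA functional
#' similarities, node2vec embeds the bidirected association graph, and a
#' stack of adaptive multi-order moment convolution layers with a linear
#' pair scorer is trained by full-batch Adam on the known associations
#' (positives) plus an equal number of globally sampled unconfirmed
#' pairs (negatives), minimising binary cross-entropy.
#'
#' For cross-validated performance estimation use [magmda_cv()]; this
#' function trains on all samples and is the entry point for candidate
#' ranking via [predict.magmda()] and [rank_candidates()].
#'
#' @param assoc an [association_table()] or path to a two-column TSV
#'   association list.
#' @param dis_sim,mir_sim optional disease/miRNA [similarity_matrix()]
#'   objects (labels must match `assoc`); `NULL` falls back to the GIP
#'   kernel alone.
#' @param config a [magmda_config()].
#' @return an object of class `"magmda"` with components `embeddings`
#'   (list `h_d`, `h_m`), `scorer`, `params`, `config`, `assoc`,
#'   `diagnostics`, `loss` (training-loss history), `inputs`.
#' @examples
#' synth <- synthetic_mda(n_diseases = 20, n_mirnas = 20, n_blocks = 2,
#'                        p_in = 0.6, p_out = 0.05, seed = 7)
#' cfg <- magmda_config(epochs = 5, n2v_walks = 2, n2v_walk_length = 10,
#'                      hidden_dim = 8, embed_dim = 8)
#' fit <- magmda(synth$assoc, synth$dis_sim, synth$mir_sim, cfg)
#' head(rank_candidates(fit, synth$assoc$disease_ids[1], top_n = 5))
#' @export
magmda <- function(assoc, dis_sim = NULL, mir_sim = NULL,
                   config = magmda_config()) {
  if (is.character(assoc)) assoc <- read_associations(assoc)
  stopifnot(inherits(assoc, "assoc_table"))
  cfg <- config
  inputs <- prepare_inputs(assoc, dis_sim, mir_sim, cfg)
  negatives <- sample_negatives(assoc, nrow(assoc$pairs),
                                seed = derive_seed(cfg$seed, 29L))
  pairs <- rbind(assoc$pairs, negatives)
  y <- c(rep(1, nrow(assoc$pairs)), rep(0, nrow(negatives)))
  nd <- inputs$graph$n_diseases
  fit <- fit_core(inputs$feats, inputs$adj, nd, pairs, y, cfg,
                  seed = derive_seed(cfg$seed, 0L))
  inf <- infer_embeddings(inputs$feats, inputs$adj, fit$params, cfg)
  structure(
    list(embeddings = list(h_d = inf$h[seq_len(nd), , drop = FALSE],
                           h_m = inf$h[-seq_len(nd), , drop = FALSE]),
         scorer = list(w = fit$params$w, b = fit$params$b),
         params = fit$params, config = cfg, assoc = assoc,
         diagnostics = lapply(inf$diagnostics, function(d) { d$fold <- 1L; d }),
         loss = fit$loss, inputs = inputs),
    class = "magmda")
}

#' @export
#' @method print magmda
print.magmda <- function(x, ...) {
  cat("Adaptive multi-order moment miRNA-disease association model\n")
  cat(sprintf("  %d diseases, %d miRNAs, %d known associations\n",
              length(x$assoc$disease_ids), length(x$assoc$mirna_ids),
              nrow(x$assoc$pairs)))
  cat(sprintf("  %d layers, hidden %d, moment pool 1..%d (Top-%d retained)\n",
              x$config$n_layers, x$config$hidden_dim, x$config$m_max,
              x$config$top_k))
  cat(sprintf("  trained %d epochs, final BCE %.4f\n",
              length(x$loss), utils::tail(x$loss, 1)))
  invisible(x)
}

#' @export
#' @method summary magmda
summary.magmda <- function(object, ...) {
  sel <- selection_frequency(object$diagnostics)
  cat("Training loss: start", signif(object$loss[1], 4),
      "-> final", signif(utils::tail(object$loss, 1), 4),
      sprintf("(%d epochs)\n", length(object$loss)))
  cat("Moment orders retained per layer (inference pass):\n")
  for (d in object$diagnostics)
    cat(sprintf("  layer %d: {%s}\n", d$layer,
                paste(which(d$mask == 1), collapse = ", ")))
  invisible(list(loss = object$loss, selection = sel))
}

#' Extract order-importance coefficients
#'
#' Returns the softmax order weights of every layer (the learned
#' importance of each candidate moment order at inference) together with
#' the pair-scorer weights.
#'
#' @param object a fitted [magmda()] model.
#' @param ... unused.
#' @return list with `order_weights` (layers x m_max matrix) and
#'   `scorer` (`w`, `b`).
#' @export
coef.magmda <- function(object, ...) {
  ow <- t(vapply(object$params$layers,
                 function(lp) softmax_vec(lp$alpha),
                 numeric(object$config$m_max)))
  rownames(ow) <- paste0("layer", seq_len(nrow(ow)))
  colnames(ow) <- paste0("order", seq_len(ncol(ow)))
  list(order_weights = ow, scorer = object$scorer)
}

#' Predict association probabilities for disease-miRNA pairs
#'
#' @param object a fitted [magmda()] model.
#' @param newdata data.frame (or 2-column matrix) with disease and miRNA
#'   identifiers; defaults to all known-association pairs.
#' @param ... unused.
#' @return `newdata` with an appended `score` column.
#' @export
predict.magmda <- function(object, newdata = NULL, ...) {
  assoc <- object$assoc
  if (is.null(newdata)) {
    idx <- assoc$pairs
    newdata <- data.frame(disease = assoc$disease_ids[idx[, 1L]],
                          mirna = assoc$mirna_ids[idx[, 2L]])
  } else {
    newdata <- as.data.frame(newdata)
    names(newdata)[1:2] <- c("disease", "mirna")
    di <- match(trimws(as.character(newdata$disease)), assoc$disease_ids)
    mi <- match(trimws(as.character(newdata$mirna)), assoc$mirna_ids)
    if (anyNA(di)) stop("unknown disease: ",
                        paste(unique(newdata$disease[is.na(di)]), collapse = ", "))
    if (anyNA(mi)) stop("unknown miRNA: ",
                        paste(unique(newdata$mirna[is.na(mi)]), collapse = ", "))
    idx <- cbind(di, mi)
  }
  newdata$score <- score_pairs(object$embeddings$h_d, object$embeddings$h_m,
                               idx, object$scorer)
  newdata
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA against the given disease with the trained pair
#' scorer and returns the top of the descending ranking (ties broken by
#' miRNA index), the standard way candidate miRNAs are prioritised for a
#' disease of interest.
#'
#' @param object a fitted [magmda()] model.
#' @param disease disease identifier (must be in the training universe).
#' @param top_n number of candidates to return (default 50); values
#'   `>= n_mirnas` return the full ranking.
#' @param exclude_known drop miRNAs already known to be associated with
#'   the disease (default `FALSE`: rank everything).
#' @return data.frame `rank`, `mirna`, `score`, `known`.
#' @export
rank_candidates <- function(object, disease, top_n = 50, exclude_known = FALSE) {
  stopifnot(inherits(object, "magmda"))
  assoc <- object$assoc
  di <- match(trimws(disease), assoc$disease_ids)
  if (is.na(di)) stop("unknown disease: ", disease)
  nm <- length(assoc$mirna_ids)
  idx <- cbind(rep(di, nm), seq_len(nm))
  scores <- score_pairs(object$embeddings$h_d, object$embeddings$h_m,
                        idx, object$scorer)
  known <- seq_len(nm) %in% assoc$pairs[assoc$pairs[, 1L] == di, 2L]
  ord <- order(-scores, seq_len(nm))
  out <- data.frame(mirna = assoc$mirna_ids[ord], score = scores[ord],
                    known = known[ord])
  if (exclude_known) out <- out[!out$known, , drop = FALSE]
  out <- utils::head(out, top_n)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Plot diagnostics of a fitted model or cross-validation run
#'
#' Base-graphics panels mirroring the mechanism analysis: the cumulative
#' moment-order selection frequencies and the distribution of per-node
#' attention weights per order and layer.
#'
#' @param x a [magmda()] or [magmda_cv()] object.
#' @param which `"selection"` or `"attention"`.
#' @param ... passed to the underlying plot function.
#' @return invisibly, the plotted summary table.
#' @export
plot.magmda <- function(x, which = c("selection", "attention"), ...) {
  plot_diagnostics(x$diagnostics, match.arg(which), ...)
}

#' @rdname plot.magmda
#' @export
plot.magmda_cv <- function(x, which = c("selection", "attention"), ...) {
  plot_diagnostics(x$diagnostics, match.arg(which), ...)
}

plot_diagnostics <- function(records, which, ...) {
  if (which == "selection") {
    sel <- selection_frequency(records)
    graphics::barplot(sel$counts, names.arg = seq_along(sel$counts),
                      xlab = "moment order", ylab = "times selected",
                      main = "adaptive moment-order selection", ...)
    return(invisible(sel))
  }
  at <- attention_summary(records)
  graphics::boxplot(median ~ order, data = at,
                    xlab = "moment order", ylab = "median attention weight",
                    main = "cross-order attention", ...)
  invisible(at)
}
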