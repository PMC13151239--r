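#' Generate a synthetic miRNA-disease dataset with planted structure
#'
#' Emulates the statistical shape the association model assumes: a
#' bipartite association matrix with planted block (community) signal —
#' diseases and miRNAs are assigned to `n_blocks` blocks and a pair is
#' associated with probability `p_in` when their blocks match and
#' `p_out` otherwise — plus disease/miRNA similarity matrices correlated
#' with the same blocks. Similarities are
#' `sim_signal * same_block + (1 - sim_signal) * |N(0, noise_sd)|`,
#' clipped to \[0, 1\] and symmetrised, with a random `sim_zero_frac`
#' fraction of off-diagonal entries zeroed so the GIP completion path of
#' [integrate_similarity()] is always exercised. Everything is
#' reproducible under `seed`.
#'
#' @param n_diseases,n_mirnas entity counts (default 100 each).
#' @param n_blocks number of planted blocks (default 4); entities are
#'   assigned to blocks of near-equal size (remainder spread
#'   round-robin).
#' @param p_in,p_out association probabilities for matched/unmatched
#'   blocks (defaults 0.5 and 0.02); `p_in = p_out` is the null model
#'   with no planted signal.
#' @param sim_signal strength of the block signal in the similarity
#'   matrices, in \[0, 1\] (default 0.7).
#' @param noise_sd standard deviation of the half-normal similarity
#'   noise (default 0.15).
#' @param sim_zero_frac fraction of off-diagonal similarity entries set
#'   to zero (default 0.3).
#' @param seed RNG seed.
#' @return list with `assoc` ([association_table()]), `dis_sim`,
#'   `mir_sim` ([similarity_matrix()] objects), `blocks` (list of block
#'   labels per disease/miRNA) and `spec` (the generating parameters).
#' @export
synthetic_mda <- function(n_diseases = 100, n_mirnas = 100, n_blocks = 4,
                          p_in = 0.5, p_out = 0.02, sim_signal = 0.7,
                          noise_sd = 0.15, sim_zero_frac = 0.3, seed = 1234) {
  if (!(p_out <= p_in)) stop("p_out must not exceed p_in")
  if (p_in == 0 && p_out == 0) stop("degenerate spec: p_in = p_out = 0")
  if (sim_signal < 0 || sim_signal > 1) stop("sim_signal must be in [0, 1]")
  local_seed(seed, {
    bd <- sort(rep_len(seq_len(n_blocks), n_diseases))
    bm <- sort(rep_len(seq_len(n_blocks), n_mirnas))
    same <- outer(bd, bm, `==`)
    p <- ifelse(same, p_in, p_out)
    amat <- matrix(stats::rbinom(n_diseases * n_mirnas, 1L, p),
                   n_diseases, n_mirnas)
    if (sum(amat) == 0L) stop("generated association matrix is empty; increase p_in")
    d_ids <- sprintf("d%03d", seq_len(n_diseases))
    m_ids <- sprintf("m%03d", seq_len(n_mirnas))
    idx <- which(amat == 1L, arr.ind = TRUE)
    assoc <- association_table(
      data.frame(d_ids[idx[, 1L]], m_ids[idx[, 2L]]),
      disease_levels = d_ids, mirna_levels = m_ids)
    dis_sim <- block_similarity(bd, sim_signal, noise_sd, sim_zero_frac, d_ids)
    mir_sim <- block_similarity(bm, sim_signal, noise_sd, sim_zero_frac, m_ids)
    list(assoc = assoc, dis_sim = dis_sim, mir_sim = mir_sim,
         blocks = list(disease = bd, mirna = bm),
         spec = list(n_diseases = n_diseases, n_mirnas = n_mirnas,
                     n_blocks = n_blocks, p_in = p_in, p_out = p_out,
                     sim_signal = sim_signal, noise_sd = noise_sd,
                     sim_zero_frac = sim_zero_frac, seed = seed))
  })
}

block_similarity <- function(blocks, sim_signal, noise_sd, zero_frac, ids) {
  n <- length(blocks)
  noise <- matrix(abs(stats::rnorm(n * n, 0, noise_sd)), n, n)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  s <- sim_signal * outer(blocks, blocks, `==`) + (1 - sim_signal) * noise
  s <- pmin(pmax(s, 0), 1)
  if (zero_frac > 0) {
    up <- which(upper.tri(s))
    drop <- sample(up, floor(zero_frac * length(up)))
    s[drop] <- 0
    s <- pmin(s, t(s))   # keep the zeroing symmetric
  }
  diag(s) <- 1
  similarity_matrix(s, ids)
}

#' Write a synthetic dataset in the pipeline's file formats
#'
#' Emits `associations.tsv`, `disease_similarity.tsv` and
#' `mirna_similarity.tsv` (the same formats [read_associations()] and
#' [read_similarity()] consume) plus `blocks.tsv` with the ground-truth
#' block labels.
#'
#' @param synth a [synthetic_mda()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(synth$assoc, file.path(dir, "associations.tsv"))
  write_similarity(synth$dis_sim, file.path(dir, "disease_similarity.tsv"))
  write_similarity(synth$mir_sim, file.path(dir, "mirna_similarity.tsv"))
  blocks <- data.frame(
    id = c(synth$assoc$disease_ids, synth$assoc$mirna_ids),
    type = rep(c("disease", "mirna"),
               c(length(synth$blocks$disease), length(synth$blocks$mirna))),
    block = c(synth$blocks$disease, synth$blocks$mirna))
  utils::write.table(blocks, file.path(dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' End-to-end held-out evaluation on a synthetic dataset
#'
#' Runs the complete pipeline (similarity integration, graph
#' construction, node2vec, adaptive moment model training) on a
#' synthetic dataset and reports held-out performance — the workhorse
#' behind the package's learning-behaviour checks.
#'
#' @param synth a [synthetic_mda()] result.
#' @param config a [magmda_config()].
#' @param folds fold indices to evaluate (default all `config$cv_k`
#'   folds); evaluating a single fold is a cheap proxy when sweeping
#'   seeds.
#' @return list with `auc` (mean over evaluated folds), `aupr`,
#'   `per_fold` (data.frame of fold metrics) and `cv` (the underlying
#'   [magmda_cv()] object).
#' @export
holdout_eval <- function(synth, config = magmda_config(), folds = NULL) {
  cv <- magmda_cv(synth$assoc, synth$dis_sim, synth$mir_sim, config,
                  folds = folds)
  per_fold <- summary(cv)$per_fold
  list(auc = mean(per_fold$auc), aupr = mean(per_fold$aupr),
       per_fold = per_fold, cv = cv)
}
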