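#' Moment-order selection frequencies across folds and layers
#'
#' Aggregates the per-fold, per-layer selection records captured at each
#' fold's final inference pass: how many times each candidate moment
#' order was selected, and the mean number of orders used per layer.
#' Two counting rules are available: `"mask"` counts an order whenever
#' the Top-K mask retained it (so the per-record count is exactly
#' `min(K, m_max)`), while `"gate"` additionally requires its gate to
#' clear 0.5, so a retained order that the dynamic threshold effectively
#' switches off is not counted — under this rule the mean can drop below
#' K.
#'
#' @param records list of selection records (the `diagnostics` component
#'   of a [magmda_cv()] or [magmda()] object), each with elements
#'   `mask`, `gates`, `w`, `layer`, `fold`.
#' @param mode counting rule, `"mask"` (default) or `"gate"`.
#' @return list with `counts` (per-order selection counts),
#'   `mean_per_layer` (mean selected orders per (fold, layer) record),
#'   `n_records`, `mode`.
#' @export
selection_frequency <- function(records, mode = c("mask", "gate")) {
  mode <- match.arg(mode)
  if (length(records) == 0L) stop("no selection records")
  sel <- vapply(records, function(r) {
    s <- r$mask == 1
    if (mode == "gate") s <- s & (r$gates > 0.5)
    as.numeric(s)
  }, numeric(length(records[[1L]]$mask)))
  counts <- rowSums(sel)
  list(counts = counts,
       mean_per_layer = sum(counts) / length(records),
       n_records = length(records), mode = mode)
}

#' Per-order attention-weight summary across folds and layers
#'
#' Tabulates the distribution of per-node cross-order attention weights
#' recorded at each fold's inference pass: median and interquartile
#' bounds per (fold, layer, order). Masked orders carry exactly zero
#' attention by construction and appear as all-zero rows.
#'
#' @param records as in [selection_frequency()].
#' @return data.frame with columns `fold`, `layer`, `order`, `retained`,
#'   `q25`, `median`, `q75`, `mean`.
#' @export
attention_summary <- function(records) {
  if (length(records) == 0L) stop("no selection records")
  do.call(rbind, lapply(records, function(r) {
    m <- length(r$mask)
    data.frame(fold = r$fold, layer = r$layer, order = seq_len(m),
               retained = r$mask == 1,
               q25 = r$attn_q[1L, ], median = r$attn_q[2L, ],
               q75 = r$attn_q[3L, ], mean = r$attn_mean,
               row.names = NULL)
  }))
}

#' Export diagnostics tables as TSV
#'
#' Writes the order-frequency table (both counting modes) and the
#' attention-quantile table.
#'
#' @param records as in [selection_frequency()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_diagnostics <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- selection_frequency(records, "mask")
  fg <- selection_frequency(records, "gate")
  freq <- data.frame(order = seq_along(fm$counts),
                     count_mask = fm$counts, count_gate = fg$counts)
  utils::write.table(freq, file.path(dir, "order_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attention_summary(records),
                     file.path(dir, "attention_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
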