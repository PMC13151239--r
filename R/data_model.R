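#' Construct an association table
#'
#' An association table is the core labelled data structure of the package:
#' an ordered set of disease identifiers, an ordered set of miRNA
#' identifiers, and a deduplicated set of (disease, miRNA) index pairs
#' marking experimentally supported associations.
#'
#' Identifiers are whitespace-trimmed and matched exactly (case preserved);
#' no fuzzy name normalisation is attempted. Identifier order is
#' first-appearance order unless explicit level vectors are given.
#'
#' @param pairs a two-column data.frame (or matrix) of character
#'   identifiers, first column diseases, second column miRNAs; one row per
#'   association. Duplicate rows are collapsed.
#' @param disease_levels,mirna_levels optional ordered identifier vectors
#'   fixing the universe of diseases/miRNAs (useful when some entities have
#'   no association). Defaults to first-appearance order of `pairs`.
#' @return an object of class `"assoc_table"` with components
#'   `disease_ids`, `mirna_ids` (character vectors) and `pairs` (integer
#'   matrix with columns `disease`, `mirna`, 1-based indices).
#' @export
association_table <- function(pairs, disease_levels = NULL, mirna_levels = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("`pairs` must have two columns (disease, miRNA)")
  d <- trimws(as.character(pairs[[1L]]))
  m <- trimws(as.character(pairs[[2L]]))
  if (any(d == "") || any(m == "")) stop("empty identifier in association pairs")
  disease_ids <- if (is.null(disease_levels)) unique(d) else trimws(as.character(disease_levels))
  mirna_ids <- if (is.null(mirna_levels)) unique(m) else trimws(as.character(mirna_levels))
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA identifiers")
  di <- match(d, disease_ids)
  mi <- match(m, mirna_ids)
  if (anyNA(di)) stop("disease identifiers not in `disease_levels`: ",
                      paste(unique(d[is.na(di)]), collapse = ", "))
  if (anyNA(mi)) stop("miRNA identifiers not in `mirna_levels`: ",
                      paste(unique(m[is.na(mi)]), collapse = ", "))
  key <- (di - 1) * length(mirna_ids) + mi
  keep <- !duplicated(key)
  out <- structure(
    list(disease_ids = disease_ids,
         mirna_ids = mirna_ids,
         pairs = cbind(disease = di[keep], mirna = mi[keep])),
    class = "assoc_table")
  out
}

#' @export
#' @method print assoc_table
print.assoc_table <- function(x, ...) {
  cat(sprintf("miRNA-disease association table: %d diseases x %d miRNAs, %d associations\n",
              length(x$disease_ids), length(x$mirna_ids), nrow(x$pairs)))
  invisible(x)
}

#' Read an association list from a tab-separated file
#'
#' Expects two-column tab-separated text, one `disease<TAB>miRNA` record
#' per line. A single header line is tolerated and detected by the
#' conventional column names (`disease`, `mirna`/`miRNA`). Duplicated
#' records are stored once; identifier order is first-appearance order.
#'
#' @param path path to the file.
#' @return an [association_table()].
#' @export
read_associations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed association line %d in %s (expected 2 tab-separated fields): %s",
                 bad[1L], path, lines[bad[1L]]))
  first <- tolower(trimws(fields[[1L]][1:2]))
  if (first[1L] %in% c("disease", "disease_id") &&
      first[2L] %in% c("mirna", "mirna_id", "miRNA")) {
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("association file contains only a header: ", path)
  }
  d <- vapply(fields, `[[`, character(1L), 1L)
  m <- vapply(fields, `[[`, character(1L), 2L)
  association_table(data.frame(d, m, stringsAsFactors = FALSE))
}

#' Write an association list as tab-separated text
#'
#' Records are emitted in the canonical order implied by the table
#' (ascending disease index, then miRNA index) so output is deterministic.
#'
#' @param assoc an [association_table()].
#' @param path output path.
#' @param header write a `disease<TAB>mirna` header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path, header = TRUE) {
  stopifnot(inherits(assoc, "assoc_table"))
  p <- assoc$pairs
  ord <- order(p[, "disease"], p[, "mirna"])
  rows <- paste(assoc$disease_ids[p[ord, "disease"]],
                assoc$mirna_ids[p[ord, "mirna"]], sep = "\t")
  if (header) rows <- c("disease\tmirna", rows)
  writeLines(rows, path)
  invisible(path)
}

#' Construct a labelled similarity matrix
#'
#' Validates the contract every similarity matrix in the pipeline obeys:
#' square, labelled, symmetric and with all entries in \[0, 1\].
#'
#' @param values numeric square matrix.
#' @param labels character labels (defaults to rownames of `values`).
#' @param check_diagonal require unit diagonal (used for GIP-derived
#'   matrices where self-similarity is exactly 1). Default `FALSE`.
#' @param tol symmetry tolerance.
#' @return a labelled numeric matrix of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(values, labels = rownames(values),
                              check_diagonal = FALSE, tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(labels)) stop("similarity matrix must be labelled")
  labels <- trimws(as.character(labels))
  if (length(labels) != nrow(values)) stop("label length does not match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate similarity labels")
  bad <- which(values < -1e-6 | values > 1 + 1e-6, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("similarity entry out of [0,1] at (%s, %s): %g",
                 labels[bad[1L, 1L]], labels[bad[1L, 2L]], values[bad[1L, , drop = FALSE]]))
  # tiny numerical spill is clipped, anything larger errored above
  values[values < 0] <- 0
  values[values > 1] <- 1
  if (max(abs(values - t(values))) > tol)
    stop("similarity matrix is asymmetric beyond tolerance ", format(tol))
  values <- (values + t(values)) / 2
  if (check_diagonal && max(abs(diag(values) - 1)) > tol)
    stop("similarity matrix diagonal must be 1")
  dimnames(values) <- list(labels, labels)
  class(values) <- c("similarity_matrix", class(values))
  values
}

#' Read a labelled similarity matrix from dense TSV
#'
#' The file format is a dense numeric matrix with a header row and a
#' leading label column (as written by [write_similarity()]). Rows and
#' columns are reordered to `expected_labels`; any expected label missing
#' from the file is an error naming the offenders.
#'
#' @param path path to the TSV file.
#' @param expected_labels ordered labels the matrix must cover; `NULL`
#'   keeps file order.
#' @return a [similarity_matrix()].
#' @export
read_similarity <- function(path, expected_labels = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labs <- trimws(as.character(df[[1L]]))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  colnames(vals) <- trimws(colnames(vals))
  if (nrow(vals) != ncol(vals))
    stop("similarity file is not square: ", nrow(vals), " rows, ", ncol(vals), " value columns")
  if (!identical(labs, colnames(vals)))
    stop("row labels and column labels disagree in ", path)
  rownames(vals) <- labs
  if (!is.null(expected_labels)) {
    expected_labels <- trimws(as.character(expected_labels))
    missing <- setdiff(expected_labels, labs)
    if (length(missing) > 0L)
      stop("similarity file is missing labels: ", paste(missing, collapse = ", "))
    vals <- vals[expected_labels, expected_labels, drop = FALSE]
  }
  similarity_matrix(vals, rownames(vals), tol = 1e-6)
}

#' Write a labelled similarity matrix as dense TSV
#'
#' @param sim a [similarity_matrix()] (or labelled square matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  labs <- rownames(sim)
  header <- paste(c("label", labs), collapse = "\t")
  body <- vapply(seq_along(labs), function(i)
    paste(c(labs[i], format(unclass(sim)[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Binary interaction-profile matrix of an association table
#'
#' The interaction profile of a disease is the 0/1 indicator vector over
#' all miRNAs of its known associations (and symmetrically for miRNAs over
#' diseases). These profiles are the inputs to the GIP kernel.
#'
#' @param assoc an [association_table()].
#' @param axis `"disease"` for a diseases x miRNAs matrix, `"mirna"` for
#'   its transpose.
#' @return a labelled 0/1 matrix.
#' @export
to_profile_matrix <- function(assoc, axis = c("disease", "mirna")) {
  stopifnot(inherits(assoc, "assoc_table"))
  axis <- match.arg(axis)
  nd <- length(assoc$disease_ids)
  nm <- length(assoc$mirna_ids)
  prof <- matrix(0, nd, nm, dimnames = list(assoc$disease_ids, assoc$mirna_ids))
  prof[assoc$pairs] <- 1
  if (axis == "mirna") prof <- t(prof)
  prof
}
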