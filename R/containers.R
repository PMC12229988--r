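#' Construct an omics block
#'
#' A named feature-by-sample numeric matrix for one omic (e.g. expression,
#' miRNA, methylation, or a network degree matrix recast as features).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param name Label for the omic.
#' @param feature_ids,sample_ids Optional identifiers; default to the
#'   dimnames of `values`, or generated identifiers when absent.
#' @return An object of class `omics_block` with elements `name` and
#'   `values` (a matrix carrying feature/sample identifiers as dimnames).
#' @export
omics_block <- function(values, name = "omic",
                        feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- feature_ids %||% rownames(values) %||% .make_ids("f", nrow(values))
  sample_ids <- sample_ids %||% colnames(values) %||% .make_ids("s", ncol(values))
  if (length(feature_ids) != nrow(values) || anyDuplicated(feature_ids)) {
    stop("feature identifiers must be unique and match the number of rows")
  }
  if (length(sample_ids) != ncol(values) || anyDuplicated(sample_ids)) {
    stop("sample identifiers must be unique and match the number of columns")
  }
  if (!all(is.finite(values))) stop("omics block contains non-finite values")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(name = name, values = values), class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block> '%s': %d features x %d samples\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

.block_values <- function(x) {
  if (inherits(x, "omics_block")) x$values else as.matrix(x)
}

#' Construct a survival table
#'
#' @param sample_id Character vector of sample identifiers (unique).
#' @param time Positive follow-up times (arbitrary units).
#' @param event 0/1 event indicators (1 = event observed, 0 = censored).
#' @return A `data.frame` of class `survival_table` with columns
#'   `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample identifiers in survival table")
  if (length(time) != length(sample_id) || length(event) != length(sample_id)) {
    stop("sample_id, time and event must have equal length")
  }
  if (any(!is.finite(time)) || any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  structure(
    data.frame(sample_id = sample_id, time = as.numeric(time),
               event = as.integer(event), stringsAsFactors = FALSE),
    class = c("survival_table", "data.frame")
  )
}

#' Construct a TF-by-gene motif prior
#'
#' Sequence-based prior of potential TF-gene interactions (typically 0/1
#' before normalization) used to seed aggregate network inference.
#'
#' @param weights TF x gene numeric matrix.
#' @param tf_ids,gene_ids Optional identifiers (default: dimnames).
#' @return An object of class `motif_prior`.
#' @export
motif_prior <- function(weights, tf_ids = NULL, gene_ids = NULL) {
  weights <- as.matrix(weights)
  tf_ids <- tf_ids %||% rownames(weights) %||% .make_ids("TF", nrow(weights))
  gene_ids <- gene_ids %||% colnames(weights) %||% .make_ids("G", ncol(weights))
  if (!all(is.finite(weights))) stop("motif prior contains non-finite values")
  dimnames(weights) <- list(tf_ids, gene_ids)
  empty <- rowSums(weights != 0) == 0
  if (any(empty)) {
    warning(sprintf("motif prior has %d TF row(s) with no supported edges: %s",
                    sum(empty), paste(utils::head(tf_ids[empty], 5), collapse = ", ")))
  }
  structure(list(weights = weights), class = "motif_prior")
}

#' Construct a TF-by-TF interaction prior
#'
#' Symmetric protein-protein interaction prior among transcription factors,
#' with unit diagonal.
#'
#' @param weights TF x TF numeric matrix.
#' @param tf_ids Optional identifiers (default: dimnames).
#' @return An object of class `ppi_prior`.
#' @export
ppi_prior <- function(weights, tf_ids = NULL) {
  weights <- as.matrix(weights)
  tf_ids <- tf_ids %||% rownames(weights) %||% .make_ids("TF", nrow(weights))
  if (nrow(weights) != ncol(weights)) stop("PPI prior must be square")
  if (!all(is.finite(weights))) stop("PPI prior contains non-finite values")
  if (max(abs(weights - t(weights))) > 1e-8) stop("PPI prior must be symmetric")
  if (max(abs(diag(weights) - 1)) > 1e-8) stop("PPI prior must have unit diagonal")
  dimnames(weights) <- list(tf_ids, tf_ids)
  structure(list(weights = weights), class = "ppi_prior")
}

#' Write / read an omics block as TSV
#'
#' Rows are features, columns samples; the first column holds feature
#' identifiers.
#'
#' @param block An `omics_block`.
#' @param path Output file path.
#' @return `write_omics_tsv` returns `path` invisibly; `read_omics_tsv`
#'   returns an `omics_block`.
#' @export
write_omics_tsv <- function(block, path) {
  .write_matrix_tsv(.block_values(block), path, id_col = "feature_id")
}

#' @rdname write_omics_tsv
#' @param name Omic label for the block read back.
#' @export
read_omics_tsv <- function(path, name = "omic") {
  omics_block(.read_matrix_tsv(path), name = name)
}

#' Write / read a survival table as TSV
#'
#' @param survival A `survival_table`.
#' @param path File path.
#' @return `write_survival_tsv` returns `path` invisibly; `read_survival_tsv`
#'   returns a `survival_table`.
#' @export
write_survival_tsv <- function(survival, path) .write_tsv(survival, path)

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  survival_table(df$sample_id, df$time, df$event)
}
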