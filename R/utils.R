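# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  }
  as.integer(round(x))
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  as.numeric(x)
}

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  sqrt(rowSums((m - rowMeans(m))^2) / (n - 1))
}

# zero-padded identifiers: S001, G042, ...
.make_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(as.character(n))), "d"), seq_len(n))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# matrix with row identifiers in the first column
.write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
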