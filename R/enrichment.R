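#' Read a GMT gene set file
#'
#' Each line holds a set name, a description, and tab-separated member
#' genes; duplicate genes within a set are stored once.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of class
#'   `gene_set_collection`, with attribute `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(), source = basename(path)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", i))
    }
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, source = basename(path))
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (unique names, non-empty
#'   sets).
#' @param source Label for the collection's origin.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "custom") {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop("gene set names must be unique and non-missing")
    }
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  }
  structure(sets, class = "gene_set_collection", source = source)
}

# weighted Kolmogorov-Smirnov running sum, exponent 1: hit steps are
# proportional to |statistic|, miss steps uniform; ES is the extreme value
.gsea_es <- function(s_abs, hit) {
  n <- length(hit)
  nh <- sum(hit)
  sh <- sum(s_abs[hit])
  inc <- numeric(n)
  inc[hit] <- if (sh > 0) s_abs[hit] / sh else 1 / nh
  if (n > nh) inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak)
}

#' Preranked gene set enrichment analysis
#'
#' Genes are sorted by decreasing ranking statistic (feature weights in the
#' intended use); the enrichment score of a set is the extreme deviation of
#' a weighted Kolmogorov-Smirnov running sum (exponent 1: hit increments
#' proportional to the absolute statistic, miss decrements uniform). The
#' null is built by gene-label permutation; p-values use the
#' `(b + 1) / (n + 1)` convention against same-sign null scores and are
#' therefore never 0; the normalized score is the ES divided by the mean
#' absolute null ES of matching sign. BH correction is applied across the
#' tested sets.
#'
#' @param weights Named numeric ranking statistic, one value per gene.
#' @param sets A `gene_set_collection` or named list of gene vectors.
#' @param n_perm Number of gene-label permutations (>= 100).
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranked universe; sets outside them are skipped.
#' @param seed RNG seed for the permutations.
#' @return A `data.frame` with one row per tested set: `set`, `size`,
#'   `es`, `nes`, `p`, `fdr`, `leading_edge` (list column).
#' @export
gsea_preranked <- function(weights, sets, n_perm = 1000, min_size = 15,
                           max_size = 500, seed = 13) {
  if (is.null(names(weights))) stop("`weights` must be named by gene")
  if (length(unique(weights)) == 1) {
    stop("all ranking statistics are equal; ranking undefined")
  }
  n_perm <- .check_count(n_perm, "n_perm", min = 100)
  ord <- order(-weights, names(weights))  # ties broken by identifier
  s <- weights[ord]
  s_abs <- abs(s)
  genes <- names(s)
  n <- length(genes)
  .set_seed(seed)
  rows <- list()
  for (nm in names(sets)) {
    members <- unique(sets[[nm]])
    pos <- which(genes %in% members)
    size <- length(pos)
    if (size == 0) {
      warning(sprintf("gene set '%s' has no overlap with the ranked genes; skipped", nm))
      next
    }
    if (size < min_size || size > max_size) next
    hit <- logical(n)
    hit[pos] <- TRUE
    obs <- .gsea_es(s_abs, hit)
    null_es <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, size)] <- TRUE
      .gsea_es(s_abs, h)$es
    }, numeric(1))
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
    nes <- if (length(same) > 0) obs$es / mean(abs(same)) else NA_real_
    le <- if (obs$es >= 0) {
      genes[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
    } else {
      genes[obs$peak:n][hit[obs$peak:n]]
    }
    rows[[nm]] <- data.frame(set = nm, size = size, es = obs$es, nes = nes,
                             p = p, stringsAsFactors = FALSE)
    rows[[nm]]$leading_edge <- list(le)
  }
  if (length(rows) == 0) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p)
  out <- out[, c("set", "size", "es", "nes", "p", "fdr", "leading_edge")]
  rownames(out) <- NULL
  out
}

#' Top transcription factors per survival-associated factor
#'
#' Selects, per survival-associated factor, the `n_top` TFs with the
#' highest absolute (back-mapped outdegree) weights; boundary ties are
#' broken by TF identifier order so the output is deterministic.
#'
#' @param outdegree_weights TFs x K weight matrix with TF rownames (e.g.
#'   from [backmap_model()]).
#' @param saf_ids Indices (or names) of the survival-associated factors;
#'   must be non-empty.
#' @param n_top Number of TFs per factor (default 20; at most the number
#'   of TFs).
#' @return A list with `per_saf` (named list of TF vectors) and `union`.
#' @export
top_tfs <- function(outdegree_weights, saf_ids, n_top = 20) {
  w <- as.matrix(outdegree_weights)
  if (length(saf_ids) == 0) stop("`saf_ids` must be non-empty")
  n_top <- .check_count(n_top, "n_top", min = 1)
  if (n_top > nrow(w)) stop("`n_top` exceeds the number of TFs")
  if (is.null(rownames(w))) stop("`outdegree_weights` must carry TF rownames")
  per_saf <- lapply(saf_ids, function(k) {
    wk <- w[, k]
    ord <- order(-abs(wk), rownames(w))
    rownames(w)[ord[seq_len(n_top)]]
  })
  names(per_saf) <- colnames(w)[saf_ids] %||% paste0("SAF", saf_ids)
  list(per_saf = per_saf, union = unique(unlist(per_saf)), n_top = n_top)
}

#' Fisher overlap test between two feature sets
#'
#' Builds the 2x2 table of a shared universe (`a = |A and B|`,
#' `b = |A \\ B|`, `c = |B \\ A|`, `d` the remainder), reports the sample
#' odds ratio `ad / bc` (infinite when `bc = 0` with non-zero numerator),
#' and the one-sided "greater" p-value from the exact hypergeometric tail;
#' a two-sided alternative is available.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all candidate features.
#' @param alternative "greater" (default, overlap larger than chance) or
#'   "two.sided".
#' @return An object of class `tf_overlap` with the contingency counts,
#'   `odds_ratio`, `p` and `universe_size`.
#' @export
overlap_fisher <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  off <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(off) > 0) {
    stop("sets are not contained in the universe; offenders: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- length(universe) - a - b - c_
  num <- a * d
  den <- b * c_
  odds <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  if (alternative == "greater") {
    p <- stats::phyper(a - 1, length(set_a), length(universe) - length(set_a),
                       length(set_b), lower.tail = FALSE)
  } else {
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2),
                            alternative = "two.sided")$p.value
  }
  structure(list(a = a, b = b, c = c_, d = d,
                 universe_size = length(universe), odds_ratio = odds, p = p,
                 alternative = alternative),
            class = "tf_overlap")
}

#' @export
print.tf_overlap <- function(x, ...) {
  cat(sprintf("<tf_overlap> a=%d b=%d c=%d d=%d (|U|=%d); OR = %.3g, p = %.3g (%s)\n",
              x$a, x$b, x$c, x$d, x$universe_size, x$odds_ratio, x$p,
              x$alternative))
  invisible(x)
}
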