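#' Univariate Cox proportional hazards fit for one covariate
#'
#' Fits `Surv(time, event) ~ x` by partial likelihood (Efron tie handling
#' by default) and reports the hazard coefficient with its Wald test.
#' A constant covariate is a degenerate case returning `beta = 0, p = 1`
#' with a warning.
#'
#' @param x Numeric covariate (e.g. one factor's scores), optionally named
#'   by sample; when named, it is aligned to the survival table.
#' @param survival A `survival_table`.
#' @param ties Tie handling: "efron" (default) or "breslow".
#' @return A list with `beta`, `se`, `z`, `p`, `n`, `n_events`.
#' @export
cox_univariate <- function(x, survival, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!is.null(names(x))) {
    idx <- match(survival$sample_id, names(x))
    if (anyNA(idx)) stop("survival table contains samples absent from `x`")
    x <- x[idx]
  }
  if (length(x) != nrow(survival)) stop("`x` length does not match the survival table")
  if (any(!is.finite(x))) stop("`x` must be finite")
  n_events <- sum(survival$event)
  if (n_events < 2) stop("at least two events are required for a Cox fit")
  if (stats::sd(x) == 0) {
    warning("constant covariate; returning beta = 0, p = 1")
    return(list(beta = 0, se = NA_real_, z = NA_real_, p = 1,
                n = length(x), n_events = n_events))
  }
  fit <- survival::coxph(survival::Surv(survival$time, survival$event) ~ x,
                         ties = ties)
  co <- summary(fit)$coefficients
  list(beta = unname(co[1, "coef"]), se = unname(co[1, "se(coef)"]),
       z = unname(co[1, "z"]), p = unname(co[1, "Pr(>|z|)"]),
       n = length(x), n_events = n_events)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjusted p-values, capped at 1 and monotone in the
#' sorted order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Associate latent factors with survival
#'
#' One univariate Cox fit per factor, Benjamini-Hochberg correction across
#' the factors, and a survival-associated-factor (SAF) flag at the FDR
#' threshold. Samples missing from the survival table (or with missing
#' time/event) are dropped and counted.
#'
#' @param model A `factor_model` or samples x K score matrix with sample
#'   rownames.
#' @param survival A `survival_table`.
#' @param fdr_threshold SAF significance threshold on the adjusted values
#'   (default 0.05).
#' @param ties Cox tie handling.
#' @return A `data.frame` of class `survival_assoc_table` with one row per
#'   factor (`beta`, `se`, `z`, `p`, `fdr`, `saf`), and attributes
#'   `n_samples`, `n_events`, `n_dropped`.
#' @export
survival_assoc_table <- function(model, survival, fdr_threshold = 0.05,
                                 ties = "efron") {
  z <- .model_scores(model)
  surv <- survival[is.finite(survival$time) & !is.na(survival$event), , drop = FALSE]
  keep <- surv$sample_id %in% rownames(z)
  n_dropped <- (nrow(survival) - nrow(surv)) + sum(!keep) +
    sum(!(rownames(z) %in% surv$sample_id[keep]))
  surv <- surv[keep, , drop = FALSE]
  if (n_dropped > 0) {
    message(sprintf("survival association: %d sample(s) dropped (missing data or no overlap)",
                    n_dropped))
  }
  z <- z[surv$sample_id, , drop = FALSE]
  fits <- lapply(seq_len(ncol(z)), function(k) {
    cox_univariate(z[, k], surv, ties = ties)
  })
  p <- vapply(fits, `[[`, numeric(1), "p")
  fdr <- adjust_bh(p)
  out <- data.frame(
    factor = colnames(z) %||% paste0("Factor", seq_len(ncol(z))),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    z = vapply(fits, `[[`, numeric(1), "z"),
    p = p, fdr = fdr, saf = fdr < fdr_threshold,
    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- nrow(surv)
  attr(out, "n_events") <- sum(surv$event)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("survival_assoc_table", "data.frame")
  out
}

#' Associate latent factors with categorical clinical features
#'
#' Binary features are tested with a two-sided Wilcoxon rank-sum test on
#' the factor values; features with more than two levels with a
#' Kruskal-Wallis test. Single-level features are skipped with a warning.
#' BH correction is applied across all (factor, feature) pairs tested.
#'
#' @param model A `factor_model` or score matrix.
#' @param clinical `data.frame` of categorical features, rownames = sample
#'   identifiers.
#' @return A `data.frame` with columns `factor`, `feature`, `test`
#'   ("wilcoxon" or "kruskal"), `statistic`, `p`, `fdr`.
#' @export
clinical_assoc <- function(model, clinical) {
  z <- .model_scores(model)
  shared <- intersect(rownames(z), rownames(clinical))
  if (length(shared) < 4) stop("fewer than 4 samples shared with the clinical table")
  z <- z[shared, , drop = FALSE]
  clinical <- clinical[shared, , drop = FALSE]
  rows <- list()
  for (feat in colnames(clinical)) {
    g <- factor(clinical[[feat]])
    g <- droplevels(g[!is.na(g)])
    if (nlevels(g) < 2) {
      warning(sprintf("clinical feature '%s' has a single level; skipped", feat))
      next
    }
    for (k in seq_len(ncol(z))) {
      xk <- z[!is.na(clinical[[feat]]), k]
      if (nlevels(g) == 2) {
        ht <- stats::wilcox.test(xk ~ g, exact = FALSE)
        test <- "wilcoxon"
      } else {
        ht <- stats::kruskal.test(xk ~ g)
        test <- "kruskal"
      }
      rows[[length(rows) + 1]] <- data.frame(
        factor = colnames(z)[k], feature = feat, test = test,
        statistic = unname(ht$statistic), p = ht$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no testable clinical features")
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier median split on a factor
#'
#' Splits samples at the factor median (ties to the low group), estimates
#' per-group product-limit survival curves and tests the difference with a
#' two-group log-rank test.
#'
#' @param x Factor values, named by sample or in survival-table order.
#' @param survival A `survival_table`.
#' @return An object of class `km_split` with `groups` (named assignment),
#'   `curves` (group, time, n_risk, n_event, surv; each curve starts at
#'   time 0 with survival 1), `chisq` and `p` (log-rank).
#' @export
km_median_split <- function(x, survival) {
  if (!is.null(names(x))) {
    idx <- match(survival$sample_id, names(x))
    if (anyNA(idx)) stop("survival table contains samples absent from `x`")
    x <- x[idx]
  }
  if (length(x) < 4) stop("median split requires at least 4 samples")
  med <- stats::median(x)
  grp <- factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
  if (any(table(grp) == 0)) {
    stop("median split produced an empty group (values tied at the median)")
  }
  df <- data.frame(time = survival$time, event = survival$event, grp = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  sdiff <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  p <- stats::pchisq(sdiff$chisq, df = 1, lower.tail = FALSE)
  strata <- rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       stringsAsFactors = FALSE)
  starts <- data.frame(group = sub("^grp=", "", names(fit$strata)), time = 0,
                       n_risk = as.vector(table(grp)[sub("^grp=", "", names(fit$strata))]),
                       n_event = 0, surv = 1, stringsAsFactors = FALSE)
  curves <- rbind(starts, curves)
  curves <- curves[order(curves$group, curves$time), ]
  rownames(curves) <- NULL
  structure(list(groups = stats::setNames(as.character(grp), survival$sample_id),
                 curves = curves, chisq = unname(sdiff$chisq), p = p),
            class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("<km_split> log-rank chisq = %.3f, p = %.3g\n", x$chisq, x$p))
  invisible(x)
}

#' @export
plot.km_split <- function(x, ..., col = c("#2166AC", "#B2182B")) {
  groups <- unique(x$curves$group)
  plot(NA, xlim = range(x$curves$time), ylim = c(0, 1),
       xlab = "Time", ylab = "Survival probability", ...)
  for (i in seq_along(groups)) {
    cu <- x$curves[x$curves$group == groups[i], ]
    graphics::lines(cu$time, cu$surv, type = "s", col = col[i], lwd = 2)
  }
  graphics::legend("topright", legend = groups, col = col[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(x)
}
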