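# Paired comparison of classifiers: the four-fold contingency table of
# misclassifications, McNemar's chi-square on the discordant counts, the
# step-up FDR procedure over all pairwise hypotheses, error rates and a
# two-sample Kolmogorov-Smirnov utility.

#' Four-fold contingency table of two classifiers
#'
#' Counts over shared test items: `a11` misclassified by both, `a12` by model
#' a only, `a21` by model b only, `a22` by neither.
#'
#' @param preds_a,preds_b predicted labels (final timestep) of the two models.
#' @param truth true labels.
#' @return object of class `contingency_table` (named list of the 4 counts).
#' @export
contingency <- function(preds_a, preds_b, truth) {
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth))
    occ_error("occrnn_shape_error", "prediction/truth lengths differ")
  wrong_a <- preds_a != truth
  wrong_b <- preds_b != truth
  structure(list(a11 = sum(wrong_a & wrong_b),
                 a12 = sum(wrong_a & !wrong_b),
                 a21 = sum(!wrong_a & wrong_b),
                 a22 = sum(!wrong_a & !wrong_b)),
            class = "contingency_table")
}

#' McNemar's chi-square test on a contingency table
#'
#' `chi2 = (a12 - a21)^2 / (a12 + a21)` (uncorrected by default), compared
#' against the chi-square distribution with 1 degree of freedom. When both
#' discordant counts are zero there is no evidence of a difference: the
#' statistic is reported as 0 with p = 1 and `degenerate = TRUE`.
#'
#' @param table a [contingency()] table (or list with `a12`, `a21`).
#' @param correction apply the continuity correction `(|a12-a21|-1)^2`.
#' @return list: `chi2`, `p`, `degenerate`.
#' @export
mcnemar_chi2 <- function(table, correction = FALSE) {
  d <- table$a12 + table$a21
  if (d == 0)
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  num <- abs(table$a12 - table$a21)
  if (correction) num <- max(num - 1, 0)
  chi2 <- num^2 / d
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Step-up false-discovery-rate control
#'
#' Sorts the p-values ascending, finds the largest rank `k` with
#' `P(k) <= (k/m) q`, and rejects the hypotheses of ranks `1..k` (none if no
#' such rank exists).
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical vector of rejection decisions, in input order.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1))
    occ_error("occrnn_domain_error", "p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  sorted <- pvalues[ord]
  ok <- which(sorted <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(ok) > 0) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}

#' Classification error rate
#' @param preds predicted labels (final timestep).
#' @param truth true labels.
#' @return fraction of mismatches in \[0, 1\].
#' @export
error_rate <- function(preds, truth) {
  if (length(preds) == 0)
    occ_error("occrnn_domain_error", "empty prediction vector")
  if (length(preds) != length(truth))
    occ_error("occrnn_shape_error", "prediction/truth lengths differ")
  mean(preds != truth)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Library-backed wrapper; the `alternative` follows the convention of the
#' distributions themselves: `"greater"` tests whether `x` is stochastically
#' greater than `y` (its ECDF lies below).
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return list: `D` statistic, `p` value.
#' @export
ks_two_sample <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0)
    occ_error("occrnn_domain_error", "empty sample")
  alt <- switch(alternative, two_sided = "two.sided",
                greater = "less",   # x stochastically greater: ECDF_x below
                less = "greater")
  kt <- suppressWarnings(ks.test(x, y, alternative = alt))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' All pairwise McNemar comparisons with FDR control
#'
#' For `n` models builds the `n (n-1) / 2` pairwise tests on shared test items
#' (7 models give 21 hypotheses) and controls the FDR at level `q` over the
#' whole family.
#'
#' @param preds_list named list of prediction vectors (final timestep).
#' @param truth true labels.
#' @param q FDR level (default 0.05).
#' @return object of class `comparison_matrix`: data frame `pairs` with chi2,
#'   p and decision per pair, and a symmetric logical `significant` matrix.
#' @export
compare_models <- function(preds_list, truth, q = 0.05) {
  nm <- names(preds_list)
  if (is.null(nm)) nm <- paste0("model", seq_along(preds_list))
  pairs <- combn(seq_along(preds_list), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tb <- contingency(preds_list[[i1]], preds_list[[i2]], truth)
    mc <- mcnemar_chi2(tb)
    data.frame(model_a = nm[i1], model_b = nm[i2],
               a12 = tb$a12, a21 = tb$a21,
               chi2 = mc$chi2, p = mc$p, degenerate = mc$degenerate)
  })
  df <- do.call(rbind, rows)
  df$significant <- bh_fdr(df$p, q)
  sig <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (j in seq_len(nrow(df))) {
    sig[df$model_a[j], df$model_b[j]] <- df$significant[j]
    sig[df$model_b[j], df$model_a[j]] <- df$significant[j]
  }
  structure(list(pairs = df, significant = sig, q = q),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix: %d pairwise McNemar tests, FDR q = %g>\n",
              nrow(x$pairs), x$q))
  # black-square convention: filled square = significant difference
  m <- ifelse(x$significant, "■", "·")
  diag(m) <- " "
  print(m, quote = FALSE)
  invisible(x)
}
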