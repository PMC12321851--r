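# Shared statistical primitives used across the pipeline. Every test here is
# two-sided; degenerate inputs return an explicit undefined marker rather than
# a silent 0 or NA.

#' Construct a test result record
#'
#' Light container used by all hypothesis tests in the package. Not normally
#' called by users.
#'
#' @param statistic numeric test statistic (NA when undefined).
#' @param p_value two-sided p-value in `[0, 1]` (NA when undefined).
#' @param method one of `"wilcoxon_ranksum"`, `"paired_t"`, `"anova_oneway"`.
#' @param n1,n2 group sizes (for the paired t-test both equal the pair count).
#' @param exact logical; TRUE when the p-value comes from exact enumeration
#'   rather than a large-sample approximation.
#' @param undefined logical; TRUE when the statistic is undefined (e.g. zero
#'   variance) and `p_value` is NA.
#' @param note optional character note (warnings such as "zero rank variance").
#' @return an object of class `cag_test`.
#' @keywords internal
new_test_result <- function(statistic, p_value, method, n1, n2,
                            exact = NA, undefined = FALSE, note = NULL) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n1 = n1, n2 = n2, exact = exact,
         undefined = undefined, note = note),
    class = "cag_test"
  )
}

#' @export
print.cag_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %s, p = %s (n1 = %d, n2 = %d%s)%s\n",
              x$method,
              format(x$statistic), format(x$p_value), x$n1, x$n2,
              if (isTRUE(x$exact)) ", exact" else "",
              if (x$undefined) " [undefined]" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Mid-rank (average-rank) Spearman correlation: the Pearson correlation of
#' the rank-transformed vectors. The default p-value uses the t-distribution
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom; `exact = TRUE` enumerates all permutations of one vector (only
#' feasible for `n <= 8`) and is intended as a small-sample oracle mode.
#'
#' A constant input vector leaves the correlation undefined: the result then
#' carries `undefined = TRUE` with `rho` and `p` set to NA, never a silent 0.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @param exact logical; exact permutation p-value (requires `length(x) <= 8`).
#' @return list with `rho`, `p`, `n`, `undefined`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman_cor() needs vectors of length >= 3")
  if (anyNA(x) || anyNA(y)) stop("spearman_cor() does not accept missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p-value only supported for n <= 8")
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    # guard rho == +-1: p limits to 0
    if (abs(rho) >= 1 - 1e-15) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 8 in practice).
all_permutations <- function(n) {
  n <- as.integer(n)
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with the usual cumulative-minimum
#' monotonicity enforcement. Output order matches input order; `q >= p`
#' elementwise and `q <= 1`. An empty input returns an empty vector.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length and order as `pvals`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test. With `mode = "exact_if_small"` the
#' null distribution is enumerated exactly when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with tie
#' and continuity correction is used. Which route was taken is recorded in the
#' result (`exact`), so downstream reports are reproducible.
#'
#' Data with zero rank variance (all values tied) yield `p = 1` with a note.
#'
#' @param a,b numeric vectors (each length >= 1).
#' @param mode `"exact_if_small"` (default) or `"approx"`.
#' @return a [new_test_result()] record, method `"wilcoxon_ranksum"`.
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))$p_value  # exact 1/3
#' @export
wilcoxon_ranksum <- function(a, b, mode = c("exact_if_small", "approx")) {
  mode <- match.arg(mode)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(new_test_result(n1 * n2 / 2, 1, "wilcoxon_ranksum", n1, n2,
                           exact = FALSE, note = "zero rank variance"))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- mode == "exact_if_small" && (n1 + n2) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  new_test_result(wt$statistic, min(1, wt$p.value), "wilcoxon_ranksum",
                  n1, n2, exact = use_exact)
}

#' Paired t-test
#'
#' Two-sided paired t-test on case-control differences:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom. Zero
#' variance of the differences (including all-zero differences) leaves the
#' statistic undefined and is flagged, never reported as p = 0 or 1.
#'
#' @param x numeric vector: either the differences themselves, or the first
#'   member of each pair when `y` is supplied.
#' @param y optional numeric vector of second pair members.
#' @return a [new_test_result()] record, method `"paired_t"`.
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  n <- length(d)
  if (n < 3) stop("paired_t() needs at least 3 pairs")
  if (stats::sd(d) == 0) {
    return(new_test_result(NA_real_, NA_real_, "paired_t", n, n,
                           exact = FALSE, undefined = TRUE,
                           note = "zero variance of differences"))
  }
  tt <- stats::t.test(d)
  new_test_result(tt$statistic, tt$p.value, "paired_t", n, n, exact = FALSE)
}

#' One-way ANOVA
#'
#' Ordinary one-way analysis of variance of a numeric response across groups,
#' as used for cross-subtype covariate comparisons. Degenerate inputs (no
#' residual variation together with equal group means, or fewer than two
#' groups) return an undefined marker.
#'
#' @param values numeric response vector.
#' @param groups grouping factor (coerced), same length as `values`.
#' @return a [new_test_result()] record, method `"anova_oneway"`; `n1` is the
#'   number of groups and `n2` the total sample size.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  k <- nlevels(droplevels(groups))
  n <- length(values)
  if (k < 2 || stats::var(values) == 0) {
    return(new_test_result(NA_real_, NA_real_, "anova_oneway", k, n,
                           exact = FALSE, undefined = TRUE,
                           note = "degenerate groups or zero variance"))
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  fstat <- fit$`F value`[1L]
  p <- fit$`Pr(>F)`[1L]
  if (!is.finite(fstat)) {
    return(new_test_result(NA_real_, NA_real_, "anova_oneway", k, n,
                           exact = FALSE, undefined = TRUE,
                           note = "zero residual variance"))
  }
  new_test_result(fstat, p, "anova_oneway", k, n, exact = FALSE)
}

#' Rank-based AUC
#'
#' Area under the empirical ROC curve computed from the Mann-Whitney rank
#' statistic: `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`. Identical to
#' the trapezoidal area under the empirical ROC.
#'
#' @param scores_pos scores of positive-class observations.
#' @param scores_neg scores of negative-class observations.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (n1 < 1 || n2 < 1) stop("both score vectors must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Significance stars
#'
#' Star coding used throughout the reports: `*` < 0.05, `**` < 0.01,
#' `***` < 0.001, `****` < 0.0001; empty string otherwise (or for NA).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
signif_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out
}
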