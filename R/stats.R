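#' Two-sample Mann-Whitney U test
#'
#' Wrapper over [stats::wilcox.test()]. The p-value is exact (two-sided, by
#' doubling the smaller tail of the enumerated U distribution, capped at 1)
#' when the combined sample size is at most `exact_limit` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_limit largest `length(x) + length(y)` for which the exact
#'   null distribution is enumerated, default 12.
#' @return list of class `lb_test`: `statistic` (U for `x`), `p_value`,
#'   `method` (`"exact"` or `"approximate"`), `sidedness`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_limit && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(statistic = unname(res$statistic), p_value = res$p.value,
                 method = if (exact) "exact" else "approximate",
                 sidedness = "two.sided"),
            class = "lb_test")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' The standard paired analogue of the Mann-Whitney test. Zero differences
#' are dropped before ranking; the p-value is exact (two-sided by doubling)
#' for up to `exact_limit` nonzero differences without tied magnitudes,
#' normal approximation with corrections otherwise.
#'
#' @param differences numeric vector of paired differences with at least one
#'   nonzero entry.
#' @param exact_limit largest number of nonzero differences enumerated
#'   exactly, default 15.
#' @return list of class `lb_test` (statistic is W, the positive-rank sum).
#' @export
signed_rank_paired <- function(differences, exact_limit = 15) {
  d <- differences[differences != 0]
  if (!length(d)) stop("all differences are zero")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= exact_limit && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(statistic = unname(res$statistic), p_value = res$p.value,
                 method = if (exact) "exact" else "approximate",
                 sidedness = "two.sided"),
            class = "lb_test")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by the probability-mass rule (summing hypergeometric
#' probabilities no larger than the observed table's), the convention of
#' [stats::fisher.test()].
#'
#' @param tab 2x2 matrix of nonnegative integer counts, grand total `>= 1`.
#' @return list of class `lb_test` (statistic is the odds-ratio estimate).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || sum(tab) < 1) stop("counts must be >= 0, total >= 1")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(list(statistic = NA_real_, p_value = 1,
                          method = "exact", sidedness = "two.sided"),
                     class = "lb_test"))
  res <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(statistic = unname(res$estimate), p_value = res$p.value,
                 method = "exact", sidedness = "two.sided"),
            class = "lb_test")
}

#' Linear-interpolation percentile
#'
#' Type-7 quantile: index \eqn{h = (n-1) q / 100} interpolated between order
#' statistics, the default of mainstream numerical environments.
#'
#' @param values non-empty numeric vector.
#' @param q percentile in `[0, 100]`.
#' @param type quantile algorithm passed to [stats::quantile()], default 7.
#' @return the percentile value.
#' @export
percentile <- function(values, q, type = 7) {
  if (!length(values)) stop("empty vector")
  if (q < 0 || q > 100) stop("q must be in [0, 100]")
  unname(stats::quantile(values, probs = q / 100, type = type, names = FALSE))
}

#' @export
print.lb_test <- function(x, ...) {
  cat(sprintf("%s %s test: statistic = %s, p = %.5g\n",
              x$method, x$sidedness, format(x$statistic), x$p_value))
  invisible(x)
}
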