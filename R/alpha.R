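#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the positive entries of a count
#' vector, with \eqn{p_i = c_i / \sum c}. Base-2 logarithms by default, the
#' QIIME 1.x convention.
#'
#' @param counts nonnegative numeric vector with at least one positive entry.
#' @param base logarithm base, default 2.
#' @return Shannon index in `[0, log_base(#positive taxa)]`.
#' @export
shannon_index <- function(counts, base = 2) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) <= 0) stop("shannon index undefined for an all-zero vector")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1,
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} where \eqn{F_1} and
#' \eqn{F_2} are the numbers of singleton and doubleton taxa. Defined on
#' integer counts only (pre-averaging tables). The classic estimator
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} is available via `bias_corrected = FALSE`.
#'
#' @param counts nonnegative integer vector.
#' @param bias_corrected use the bias-corrected form (default `TRUE`).
#' @return estimated richness, always `>=` observed richness.
#' @export
chao1_index <- function(counts, bias_corrected = TRUE) {
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("chao1 requires integer counts")
  if (any(counts < 0)) stop("counts must be >= 0")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f1 == 0) s_obs
  else s_obs + f1^2 / (2 * max(f2, 1))
}

#' Alpha diversity averaged over a rarefaction ensemble
#'
#' Computes the chosen metric per sample on every rarefaction replicate and
#' reports the arithmetic mean over replicates (the metric is averaged, not
#' the tables). All replicates must retain the same sample set.
#'
#' @param ensemble a [rarefaction_ensemble()].
#' @param metric `"shannon"` or `"chao1"`.
#' @param base log base for Shannon, default 2.
#' @return data.frame of class `lb_alpha` with columns `sample_id`, `value`,
#'   and attributes `metric`, `reps`.
#' @export
alpha_over_ensemble <- function(ensemble, metric = c("shannon", "chao1"),
                                base = 2) {
  metric <- match.arg(metric)
  samples <- colnames(ensemble$tables[[1]])
  for (tab in ensemble$tables)
    if (!identical(colnames(tab), samples))
      stop("sample retention differs across ensemble replicates")
  fun <- switch(metric,
                shannon = function(v) shannon_index(v, base = base),
                chao1 = chao1_index)
  per_rep <- vapply(ensemble$tables,
                    function(tab) apply(unclass(tab), 2, fun),
                    numeric(length(samples)))
  per_rep <- matrix(per_rep, nrow = length(samples))
  out <- data.frame(sample_id = samples, value = rowMeans(per_rep),
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "reps") <- length(ensemble$tables)
  class(out) <- c("lb_alpha", "data.frame")
  out
}
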