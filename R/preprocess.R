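#' Remove dataset-wide singleton OTUs
#'
#' Drops taxa whose total count across the entire dataset equals exactly 1.
#' The filter is defined on raw integer counts, before any normalization or
#' rarefaction averaging; a taxon observed once in each of two samples (total
#' 2) is retained, as is an all-zero taxon (total 0).
#'
#' @param table integer-count [otu_table()].
#' @return filtered [otu_table()].
#' @export
remove_singletons <- function(table) {
  stopifnot_integer_counts(table, "remove_singletons")
  keep <- rowSums(table) != 1
  otu_table(unclass(table)[keep, , drop = FALSE])
}

#' Drop low-depth samples
#'
#' Removes samples whose total read count is below `min_reads`; a sample at
#' exactly the threshold is retained.
#'
#' @param table an [otu_table()].
#' @param min_reads minimum column sum, default 500.
#' @return filtered [otu_table()].
#' @export
filter_low_depth <- function(table, min_reads = 500) {
  keep <- colSums(table) >= min_reads
  otu_table(unclass(table)[, keep, drop = FALSE])
}

#' Rarefy an OTU table to even depth
#'
#' Each sample with at least `depth` reads is replaced by a uniform random
#' subsample of exactly `depth` reads drawn without replacement
#' (multivariate hypergeometric); samples with fewer reads are dropped.
#' Subsampling is delegated to [vegan::rrarefy()].
#'
#' @param table integer-count [otu_table()].
#' @param depth target reads per sample, default 1000.
#' @param seed integer seed; the draw is reproducible and the caller's RNG
#'   state is left untouched.
#' @return rarefied [otu_table()] whose columns all sum to `depth`.
#' @export
rarefy_table <- function(table, depth = 1000, seed) {
  if (depth <= 0) stop("depth must be a positive integer")
  stopifnot_integer_counts(table, "rarefy_table")
  keep <- colSums(table) >= depth
  sub <- round(unclass(table)[, keep, drop = FALSE])
  if (ncol(sub) == 0)
    return(otu_table(sub))
  # rrarefy heuristically warns when the smallest nonzero count exceeds 1;
  # totals are checked above, so that warning is spurious here
  rar <- withCallingHandlers(
    withr::with_seed(seed, vegan::rrarefy(t(sub), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dimnames(rar) <- list(colnames(sub), rownames(sub))
  otu_table(t(rar))
}

#' Repeated-rarefaction ensemble
#'
#' Performs `reps` independent rarefactions of the same table. Per-replicate
#' seeds are derived from the master seed by drawing `reps` integers from the
#' seeded RNG, so the ensemble is reproducible while replicates remain
#' independent. Sample retention depends only on totals and is therefore
#' identical across replicates.
#'
#' @inheritParams rarefy_table
#' @param reps number of rarefaction replicates, default 10.
#' @return list of class `lb_ensemble` with elements `tables` (list of
#'   rarefied [otu_table()]s), `depth`, `seeds`.
#' @export
rarefaction_ensemble <- function(table, depth = 1000, reps = 10, seed) {
  if (reps <= 0) stop("reps must be a positive integer")
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, reps))
  tables <- lapply(seeds, function(s) rarefy_table(table, depth, seed = s))
  structure(list(tables = tables, depth = depth, seeds = seeds),
            class = "lb_ensemble")
}

#' @export
print.lb_ensemble <- function(x, ...) {
  cat(sprintf("Rarefaction ensemble: %d replicates at depth %d, %d samples\n",
              length(x$tables), x$depth, ncol(x$tables[[1]])))
  invisible(x)
}

#' Average the tables of a rarefaction ensemble
#'
#' Element-wise mean of the replicate tables; used as the "normalized read
#' count" substrate for intensity screens and enrichment statistics.
#'
#' @param ensemble a [rarefaction_ensemble()].
#' @return real-valued [otu_table()].
#' @export
average_ensemble <- function(ensemble) {
  acc <- Reduce(`+`, lapply(ensemble$tables, unclass))
  otu_table(acc / length(ensemble$tables))
}

#' Standard preprocessing chain
#'
#' Applies the pipeline's fixed filter order: dataset-wide singleton removal
#' on the full integer table, then the minimum-read-depth sample filter, then
#' the repeated-rarefaction ensemble.
#'
#' @inheritParams rarefaction_ensemble
#' @param min_reads minimum reads per sample, default 500.
#' @return a [rarefaction_ensemble()].
#' @export
preprocess <- function(table, min_reads = 500, depth = 1000, reps = 10, seed) {
  table <- remove_singletons(table)
  table <- filter_low_depth(table, min_reads)
  rarefaction_ensemble(table, depth = depth, reps = reps, seed = seed)
}
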