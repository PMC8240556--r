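#' Negative-control percentile exceedance test
#'
#' Computes the `q`-th percentile of the alpha-diversity values of the PBS
#' buffer controls and classifies every sample as strictly above or at/below
#' that cutoff. For each non-PBS sample class, a Fisher's exact test compares
#' the above/below split of that class against the PBS controls.
#'
#' @param alpha an alpha-diversity table ([alpha_over_ensemble()] or any
#'   data.frame with `sample_id`, `value`).
#' @param metadata sample metadata covering the alpha table's samples.
#' @param q percentile of the PBS values, default 95.
#' @return list of class `lb_exceedance`: `threshold`, `flags` (data.frame
#'   `sample_id`, `sample_class`, `above`), `tests` (data.frame per class with
#'   the 2x2 counts and Fisher p).
#' @export
exceedance_test <- function(alpha, metadata, q = 95) {
  md <- metadata[match(alpha$sample_id, metadata$sample_id), ]
  if (any(is.na(md$sample_id)))
    stop("alpha values for samples missing from metadata: ",
         paste(alpha$sample_id[is.na(md$sample_id)], collapse = ", "))
  pbs_vals <- alpha$value[md$sample_class == "pbs"]
  if (length(pbs_vals) < 2) stop("need at least two PBS samples")
  threshold <- percentile(pbs_vals, q)
  flags <- data.frame(sample_id = alpha$sample_id,
                      sample_class = md$sample_class,
                      above = alpha$value > threshold,
                      stringsAsFactors = FALSE)
  pbs_above <- sum(flags$above[flags$sample_class == "pbs"])
  pbs_below <- sum(!flags$above[flags$sample_class == "pbs"])
  classes <- setdiff(unique(flags$sample_class), "pbs")
  tests <- do.call(rbind, lapply(classes, function(cl) {
    ab <- sum(flags$above[flags$sample_class == cl])
    be <- sum(!flags$above[flags$sample_class == cl])
    p <- fisher_exact_2x2(matrix(c(ab, be, pbs_above, pbs_below), 2))$p_value
    data.frame(sample_class = cl, above = ab, below = be,
               pbs_above = pbs_above, pbs_below = pbs_below,
               fisher_p = p, stringsAsFactors = FALSE)
  }))
  structure(list(threshold = threshold, q = q, flags = flags, tests = tests),
            class = "lb_exceedance")
}

#' Distances from tissues to their fetus-matched controls
#'
#' For every fetal tissue sample, the mean distance to the PBS controls that
#' share its `fetus_id` (multiple matched controls are averaged). Tissues
#' without a matched PBS control are excluded with a warning. The reference
#' set is all pairwise distances among PBS controls ("within PBS").
#'
#' @param dm a [distance_matrix()].
#' @param metadata sample metadata covering the matrix samples.
#' @return list of class `lb_matched`: `records` (data.frame `sample_id`,
#'   `fetus_id`, `organ`, `distance`), `reference` (numeric vector of
#'   PBS-to-PBS distances), `normalized` flag.
#' @export
matched_control_distances <- function(dm, metadata) {
  md <- metadata[match(rownames(dm), metadata$sample_id), ]
  pbs_ids <- md$sample_id[md$sample_class == "pbs"]
  tissue <- md[md$sample_class == "fetal_tissue", ]
  rec <- lapply(seq_len(nrow(tissue)), function(i) {
    fid <- tissue$fetus_id[i]
    matched <- pbs_ids[!is.na(md$fetus_id[match(pbs_ids, md$sample_id)]) &
                         md$fetus_id[match(pbs_ids, md$sample_id)] == fid]
    if (is.na(fid) || !length(matched)) return(NULL)
    data.frame(sample_id = tissue$sample_id[i], fetus_id = fid,
               organ = tissue$organ[i],
               distance = mean(dm[tissue$sample_id[i], matched]),
               stringsAsFactors = FALSE)
  })
  dropped <- tissue$sample_id[vapply(rec, is.null, TRUE)]
  if (length(dropped))
    warning("tissue sample(s) without matched PBS excluded: ",
            paste(dropped, collapse = ", "))
  records <- do.call(rbind, rec)
  if (is.null(records))
    records <- data.frame(sample_id = character(), fetus_id = character(),
                          organ = character(), distance = numeric())
  ref <- if (length(pbs_ids) >= 2) {
    sub <- dm[pbs_ids, pbs_ids]
    sub[upper.tri(sub)]
  } else numeric(0)
  structure(list(records = records, reference = ref, normalized = FALSE),
            class = "lb_matched")
}

#' Within-fetus normalization of matched distances
#'
#' Restricts to fetuses with at least `min_tissues` tissue records, then
#' divides each tissue-to-matched-control distance by the mean distance of
#' its fetus, so that normalized values average exactly 1 within each fetus.
#' Organ-level departures from 1 then express the surface-to-internal
#' diversity gradient independently of per-fetus baseline dissimilarity.
#'
#' @param mds a [matched_control_distances()] result.
#' @param min_tissues minimum tissue records per fetus, default 2.
#' @return an `lb_matched` object with normalized `records` and
#'   `normalized = TRUE`.
#' @export
normalize_within_fetus <- function(mds, min_tissues = 2) {
  rec <- mds$records
  keep <- ave(rec$distance, rec$fetus_id, FUN = length) >= min_tissues
  rec <- rec[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no fetus has >= ", min_tissues, " tissue records")
  means <- ave(rec$distance, rec$fetus_id, FUN = mean)
  if (any(means == 0))
    stop("fetus with all-zero matched distances (degenerate identical profiles)")
  rec$distance <- rec$distance / means
  structure(list(records = rec, reference = mds$reference, normalized = TRUE),
            class = "lb_matched")
}

#' Per-organ comparison of matched distances against the control reference
#'
#' Unpaired mode: Mann-Whitney U of each organ's tissue-to-matched-control
#' distances against the PBS-to-PBS reference distances. Paired mode (for
#' within-fetus normalized values): Wilcoxon signed-rank of each organ's
#' normalized values against 1, the within-fetus average; organs with fewer
#' than two records are skipped with a warning.
#'
#' @param mds a [matched_control_distances()] (or normalized) result.
#' @param paired use the signed-rank-vs-1 mode (default `FALSE`).
#' @return data.frame with one row per organ: `organ`, `n`, `median`,
#'   `direction`, `p_value`.
#' @export
compare_tissue_vs_reference <- function(mds, paired = FALSE) {
  rec <- mds$records
  organs <- unique(rec$organ)
  out <- lapply(organs, function(org) {
    v <- rec$distance[rec$organ == org]
    if (paired) {
      if (length(v) < 2 || all(v == 1)) {
        warning("organ '", org, "' skipped in paired mode (too few records)")
        return(NULL)
      }
      p <- signed_rank_paired(v - 1)$p_value
      dir <- if (stats::median(v) > 1) "greater" else "less"
    } else {
      if (!length(mds$reference)) stop("empty PBS reference set")
      p <- mann_whitney_u(v, mds$reference)$p_value
      dir <- if (stats::median(v) > stats::median(mds$reference))
        "greater" else "less"
    }
    data.frame(organ = org, n = length(v), median = stats::median(v),
               direction = dir, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled test of matched distances against the control reference
#'
#' One test per dataset: each tissue-to-matched-control distance is divided
#' by the mean PBS-to-PBS reference distance and the ratios are tested
#' against 1 by Wilcoxon signed-rank. A small p with `direction = "greater"`
#' says tissues are systematically more dissimilar from their matched
#' controls than the controls are from each other.
#'
#' @param mds a [matched_control_distances()] result (unnormalized).
#' @return list: `ratio_median`, `direction`, `p_value`, `n`.
#' @export
matched_vs_reference_test <- function(mds) {
  if (!length(mds$reference)) stop("empty PBS reference set")
  ratios <- mds$records$distance / mean(mds$reference)
  res <- signed_rank_paired(ratios - 1)
  list(ratio_median = stats::median(ratios),
       direction = if (stats::median(ratios) > 1) "greater" else "less",
       p_value = res$p_value, n = length(ratios))
}

#' Summarize qPCR cycle-threshold records
#'
#' Technical replicates are averaged into one final Ct per sample. Each
#' fetal organ class is then compared against the PBS controls and against a
#' designated low-signal internal-control organ by Mann-Whitney U. Lower Ct
#' means more template DNA, so `direction = "more_dna"` corresponds to a Ct
#' median below the comparator's.
#'
#' @param ct data.frame with columns `sample_id`, `ct` (one row per
#'   replicate; at least one replicate per sample, all finite).
#' @param metadata sample metadata.
#' @param internal_control organ used as internal baseline, default
#'   `"thymus"`.
#' @return list of class `lb_ct`: `per_sample` (data.frame `sample_id`,
#'   `mean_ct`, `n_replicates`), `comparisons` (data.frame `group`,
#'   `comparator`, `p_value`, `direction`).
#' @export
summarize_ct <- function(ct, metadata, internal_control = "thymus") {
  if (any(!is.finite(ct$ct))) stop("Ct replicates must all be finite")
  per_sample <- stats::aggregate(ct["ct"], by = ct["sample_id"], FUN = mean)
  names(per_sample)[2] <- "mean_ct"
  per_sample$n_replicates <-
    stats::aggregate(ct["ct"], by = ct["sample_id"], FUN = length)$ct
  md <- metadata[match(per_sample$sample_id, metadata$sample_id), ]
  vals <- function(sel) per_sample$mean_ct[sel]
  pbs <- vals(md$sample_class == "pbs")
  internal <- vals(md$organ == internal_control)
  organs <- setdiff(unique(md$organ[md$sample_class == "fetal_tissue"]), "none")
  cmp <- list()
  for (org in organs) {
    v <- vals(md$organ == org)
    if (length(v) && length(pbs))
      cmp[[length(cmp) + 1]] <- data.frame(
        group = org, comparator = "pbs",
        p_value = mann_whitney_u(v, pbs)$p_value,
        direction = if (stats::median(v) < stats::median(pbs))
          "more_dna" else "less_dna",
        stringsAsFactors = FALSE)
    if (org != internal_control && length(v) && length(internal))
      cmp[[length(cmp) + 1]] <- data.frame(
        group = org, comparator = internal_control,
        p_value = mann_whitney_u(v, internal)$p_value,
        direction = if (stats::median(v) < stats::median(internal))
          "more_dna" else "less_dna",
        stringsAsFactors = FALSE)
  }
  structure(list(per_sample = per_sample, comparisons = do.call(rbind, cmp)),
            class = "lb_ct")
}
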