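#' End-to-end contamination-aware analysis
#'
#' Orchestrates the full analysis graph on one dataset: validation,
#' preprocessing (singleton removal, depth filter, repeated rarefaction),
#' alpha diversity with the negative-control exceedance test, replicate-
#' averaged beta diversity with PCoA and PERMANOVA, matched-control
#' distances (raw and within-fetus normalized) with their organ-level tests,
#' optional qPCR Ct summaries, the genus intensity screen, and the
#' log2FC + RPA differential enrichment of the target organ. Deterministic
#' given the parameter list and master seed.
#'
#' @param table integer-count [otu_table()].
#' @param metadata sample metadata.
#' @param tree rooted `phylo` tree covering the taxa (required for weighted
#'   UniFrac; pass `NULL` to fall back to Bray-Curtis everywhere).
#' @param taxonomy a [taxonomy_table()]; when `NULL`, each taxon is treated
#'   as its own genus.
#' @param ct optional Ct replicate table (see [summarize_ct()]).
#' @param params analysis parameters; any subset of the defaults
#'   `list(min_reads = 500, depth = 1000, reps = 10, q = 95, metric =
#'   "wunifrac", normalized = FALSE, permutations = 999, target_organ =
#'   "gut", internal_control = "spleen", lfc_cut = 2, rpa_cut = 3,
#'   pseudocount = 1, theta = 0.5, min_tissues = 2)`.
#' @param seed master seed; every stochastic stage consumes a namespaced
#'   substream of it.
#' @param out_dir optional directory: when given, all result tables are
#'   written as TSV plus a JSON manifest of every parameter used.
#' @return list of class `lb_report` with elements `ensemble_average`,
#'   `alpha`, `exceedance`, `beta` (averaged distance matrix), `pcoa`,
#'   `permanova`, `matched`, `matched_normalized`, `organ_tests_unpaired`,
#'   `organ_tests_paired`, `matched_pooled_test`, `intensity`, `taxa_screen`,
#'   `enrichment`, `ct_summary`, `dropped`, `params`.
#' @export
run_pipeline <- function(table, metadata, tree = NULL, taxonomy = NULL,
                         ct = NULL, params = list(), seed = 1,
                         out_dir = NULL) {
  defaults <- list(min_reads = 500, depth = 1000, reps = 10, q = 95,
                   metric = if (is.null(tree)) "braycurtis" else "wunifrac",
                   normalized = FALSE, permutations = 999,
                   target_organ = "gut", internal_control = "spleen",
                   lfc_cut = 2, rpa_cut = 3, pseudocount = 1, theta = 0.5,
                   min_tissues = 2)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)

  report <- validate_dataset(table, metadata, tree)
  if (!report$ok)
    stop("inconsistent dataset: ",
         paste(unlist(report[1:3]), collapse = ", "))

  # preprocessing
  filtered <- filter_low_depth(remove_singletons(table), p$min_reads)
  dropped <- list(
    singleton_taxa = setdiff(rownames(table), rownames(filtered)),
    low_depth_samples = setdiff(colnames(table), colnames(filtered)))
  ens <- rarefaction_ensemble(filtered, depth = p$depth, reps = p$reps,
                              seed = seed)
  dropped$below_rarefaction_depth <-
    setdiff(colnames(filtered), colnames(ens$tables[[1]]))
  avg <- average_ensemble(ens)
  md <- metadata[metadata$sample_id %in% colnames(avg), ]

  # alpha diversity + exceedance
  alpha <- alpha_over_ensemble(ens, "shannon")
  exceed <- exceedance_test(alpha, md, q = p$q)

  # beta diversity on fetal + PBS samples, per replicate then averaged
  beta <- beta_over_ensemble(ens, metric = p$metric, tree = tree,
                             normalized = p$normalized)
  fp_ids <- md$sample_id[md$sample_class %in% c("fetal_tissue", "pbs")]
  beta_fp <- distance_matrix(unclass(beta)[fp_ids, fp_ids])
  ord <- pcoa_ordination(beta_fp)
  grouping <- ifelse(md$sample_class == "fetal_tissue", md$organ, "pbs")
  names(grouping) <- md$sample_id
  perm <- permanova(beta_fp, grouping[fp_ids],
                    permutations = p$permutations, seed = seed + 1L)

  # matched-control distances
  matched <- matched_control_distances(beta_fp, md)
  pooled <- matched_vs_reference_test(matched)
  unpaired <- compare_tissue_vs_reference(matched, paired = FALSE)
  matched_norm <- normalize_within_fetus(matched,
                                         min_tissues = p$min_tissues)
  paired <- suppressWarnings(
    compare_tissue_vs_reference(matched_norm, paired = TRUE))

  # taxa-level screens on the ensemble average
  if (is.null(taxonomy))
    taxonomy <- taxonomy_table(rownames(avg), paste0("g__", rownames(avg)))
  intensity <- genus_mean_intensity(avg, taxonomy, md)
  screen <- classify_enriched_taxa(intensity, theta = p$theta)
  enrich <- differential_enrichment(avg, md, target_organ = p$target_organ,
                                    internal_control = p$internal_control,
                                    lfc_cut = p$lfc_cut, rpa_cut = p$rpa_cut,
                                    pseudocount = p$pseudocount)

  ct_summary <- if (!is.null(ct))
    summarize_ct(ct[ct$sample_id %in% md$sample_id, , drop = FALSE], md)

  res <- structure(list(ensemble_average = avg, alpha = alpha,
                        exceedance = exceed, beta = beta, pcoa = ord,
                        permanova = perm, matched = matched,
                        matched_normalized = matched_norm,
                        organ_tests_unpaired = unpaired,
                        organ_tests_paired = paired,
                        matched_pooled_test = pooled,
                        intensity = intensity, taxa_screen = screen,
                        enrichment = enrich, ct_summary = ct_summary,
                        dropped = dropped,
                        params = c(p, seed = seed)),
                   class = "lb_report")
  if (!is.null(out_dir)) write_report(res, out_dir)
  invisible(res)
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_otu_table(res$ensemble_average,
                  file.path(out_dir, "ensemble_average.tsv"))
  tsv(res$alpha, "alpha_shannon.tsv")
  tsv(res$exceedance$tests, "exceedance_tests.tsv")
  write_distance_matrix(res$beta, file.path(out_dir, "beta_distance.tsv"))
  coords <- data.frame(sample_id = rownames(res$pcoa$coordinates),
                       res$pcoa$coordinates, check.names = FALSE)
  tsv(coords, "pcoa_coordinates.tsv")
  tsv(res$matched$records, "matched_distances.tsv")
  tsv(res$matched_normalized$records, "matched_distances_normalized.tsv")
  tsv(res$organ_tests_unpaired, "organ_tests_unpaired.tsv")
  tsv(res$organ_tests_paired, "organ_tests_paired.tsv")
  tsv(res$taxa_screen, "taxa_screen.tsv")
  tsv(res$enrichment, "enrichment.tsv")
  if (!is.null(res$ct_summary)) {
    tsv(res$ct_summary$per_sample, "ct_per_sample.tsv")
    tsv(res$ct_summary$comparisons, "ct_comparisons.tsv")
  }
  manifest <- c(res$params,
                list(permanova = res$permanova[c("statistic", "r2",
                                                 "p_value", "permutations")],
                     exceedance_threshold = res$exceedance$threshold,
                     pcoa_proportion_explained =
                       res$pcoa$proportion_explained,
                     dropped = res$dropped))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Recovery of planted signal taxa by the enrichment screen
#'
#' Runs [differential_enrichment()] once per target organ of a synthetic
#' dataset's planted signal taxa (using spleen as the internal control, or
#' thymus when spleen itself is the target) and reports, for every planted
#' taxon, whether it was flagged enriched in its own target organ.
#'
#' @param avg normalized (ensemble-average) [otu_table()].
#' @param metadata sample metadata.
#' @param truth the dataset's [truth_labels()].
#' @param ... passed to [differential_enrichment()] (cutoffs, pseudocount).
#' @return data.frame `taxon_id`, `organ`, `recovered`.
#' @export
recover_signal_taxa <- function(avg, metadata, truth, ...) {
  sig <- truth[truth$role == "signal", , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(taxon_id = character(), organ = character(),
                      recovered = logical()))
  organ <- vapply(sig$target_organs, `[`, "", 1L)
  out <- do.call(rbind, lapply(unique(organ), function(org) {
    internal <- if (org == "spleen") "thymus" else "spleen"
    enr <- differential_enrichment(avg, metadata, target_organ = org,
                                   internal_control = internal, ...)
    ids <- sig$taxon_id[organ == org]
    data.frame(taxon_id = ids, organ = org,
               recovered = ids %in% enr$taxon_id[enr$enriched],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
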