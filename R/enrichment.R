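#' Mean signal intensity per genus and sample class
#'
#' Counts are summed within genus per sample, then averaged across samples
#' within each class. Classes are the control classes (pbs, reagent,
#' environment, operator) plus, by default, one class per fetal organ;
#' `per_organ = FALSE` pools all fetal tissues into a single class. Genera
#' with zero intensity across all classes are removed, as are taxa whose
#' lineage resolves to the `"unassigned"` genus token.
#'
#' @param table an [otu_table()] (typically the rarefaction-ensemble
#'   average).
#' @param taxonomy a [taxonomy_table()] covering the table's taxa.
#' @param metadata sample metadata.
#' @param per_organ split fetal tissues by organ (default `TRUE`).
#' @return list of class `lb_intensity`: `intensity` (genus x class matrix),
#'   `class_sizes` (named integer vector), `fetal_classes` (character).
#' @export
genus_mean_intensity <- function(table, taxonomy, metadata, per_organ = TRUE) {
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  if (any(is.na(md$sample_id)))
    stop("samples missing from metadata: ",
         paste(colnames(table)[is.na(md$sample_id)], collapse = ", "))
  genus <- taxonomy$genus[match(rownames(table), taxonomy$taxon_id)]
  if (any(is.na(genus)))
    stop("taxa missing from taxonomy: ",
         paste(rownames(table)[is.na(genus)], collapse = ", "))
  keep <- genus != "unassigned"
  gtab <- rowsum(unclass(table)[keep, , drop = FALSE], genus[keep])

  cls <- ifelse(md$sample_class == "fetal_tissue",
                if (per_organ) md$organ else "fetal_tissue",
                md$sample_class)
  classes <- unique(cls)
  intensity <- vapply(classes,
                      function(cl) rowMeans(gtab[, cls == cl, drop = FALSE]),
                      numeric(nrow(gtab)))
  intensity <- matrix(intensity, nrow = nrow(gtab),
                      dimnames = list(rownames(gtab), classes))
  nonzero <- rowSums(intensity) > 0
  intensity <- intensity[nonzero, , drop = FALSE]
  fetal_classes <- if (per_organ)
    intersect(classes, setdiff(organ_levels, "none")) else
      intersect(classes, "fetal_tissue")
  structure(list(intensity = intensity,
                 class_sizes = vapply(classes,
                                      function(cl) sum(cls == cl), 0L),
                 fetal_classes = fetal_classes),
            class = "lb_intensity")
}

#' Screen genera into contaminant / signal categories
#'
#' A genus whose PBS mean intensity is greater than or equal to its maximum
#' intensity over the fetal-tissue classes is a potential contaminant
#' (`control_enriched`): reagent-borne taxa appear homogeneously in
#' everything including buffer blanks. A genus is `fetal_enriched` when its
#' PBS intensity falls below `theta` times its maximum fetal intensity (and
#' that maximum is positive); anything in between is `indeterminate`. The
#' ratio `theta` replaces the manual curation of "top" genera that a visual
#' screen would perform.
#'
#' @param git a [genus_mean_intensity()] result with a `pbs` class present.
#' @param theta ratio threshold in (0, 1], default 0.5.
#' @return data.frame `genus`, `pbs_intensity`, `max_fetal_intensity`,
#'   `label`.
#' @export
classify_enriched_taxa <- function(git, theta = 0.5) {
  ints <- git$intensity
  if (!"pbs" %in% colnames(ints)) stop("no PBS class in intensity table")
  if (!length(git$fetal_classes)) stop("no fetal classes in intensity table")
  pbs <- ints[, "pbs"]
  maxf <- apply(ints[, git$fetal_classes, drop = FALSE], 1, max)
  label <- ifelse(pbs >= maxf, "control_enriched",
                  ifelse(maxf > 0 & pbs < theta * maxf,
                         "fetal_enriched", "indeterminate"))
  data.frame(genus = rownames(ints), pbs_intensity = unname(pbs),
             max_fetal_intensity = unname(maxf), label = unname(label),
             stringsAsFactors = FALSE)
}

#' log2 fold change with pseudocount
#'
#' `log2((a + pseudocount) / (b + pseudocount))`. The pseudocount handles
#' taxa absent from one class (the plain ratio is undefined at `b = 0`);
#' as it tends to 0 with `a, b > 0` the value tends to `log2(a/b)`.
#'
#' @param a,b nonnegative normalized read counts (vectorized).
#' @param pseudocount positive stabilizer, default 1.
#' @return log2 fold change(s).
#' @export
log2_fold_change <- function(a, b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((a + pseudocount) / (b + pseudocount))
}

#' Relative percentage abundance (prevalence share)
#'
#' \eqn{RPA = 100 \, s_{target} / (s_{target} + s_{internal} +
#' s_{external})}, where each `s` counts the samples of a class in which
#' reads exist for the taxon.
#'
#' @param s_target,s_internal,s_external nonnegative sample counts
#'   (vectorized); at least one must be positive per entry.
#' @return percentage in `[0, 100]`.
#' @export
relative_percentage_abundance <- function(s_target, s_internal, s_external) {
  denom <- s_target + s_internal + s_external
  if (any(denom <= 0)) stop("all prevalence counts are zero")
  100 * s_target / denom
}

#' Differential enrichment of taxa in a target organ
#'
#' For each taxon, `A` is the mean normalized count over target-organ
#' samples and `B` the mean over the internal-control organ (a low-signal
#' fetal organ, spleen or thymus) and over the external PBS controls;
#' prevalence counts `s_*` are the numbers of samples per class with count
#' `> 0`. A taxon is flagged enriched when the log2 fold change passes
#' `lfc_cut` against **both** controls and the relative percentage abundance
#' passes `rpa_cut` (an OR rule over the two fold changes is available via
#' `rule = "or"`).
#'
#' @param table an [otu_table()] of normalized counts (typically the
#'   ensemble average).
#' @param metadata sample metadata.
#' @param target_organ organ screened for enrichment, default `"gut"`.
#' @param internal_control internal-control organ, `"spleen"` or
#'   `"thymus"`.
#' @param lfc_cut log2 fold-change cutoff, default 2.
#' @param rpa_cut relative-percentage-abundance cutoff (percent), default 3.
#' @param pseudocount stabilizer for the fold changes, default 1.
#' @param rule combine the two fold-change criteria with `"and"` (default)
#'   or `"or"`.
#' @return data.frame sorted by `rpa` then `log2fc_vs_internal`, one row per
#'   taxon with all intermediate quantities and the `enriched` flag.
#' @export
differential_enrichment <- function(table, metadata, target_organ = "gut",
                                    internal_control = c("spleen", "thymus"),
                                    lfc_cut = 2, rpa_cut = 3, pseudocount = 1,
                                    rule = c("and", "or")) {
  internal_control <- match.arg(internal_control)
  rule <- match.arg(rule)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  sel_t <- md$organ == target_organ
  sel_i <- md$organ == internal_control
  sel_e <- md$sample_class == "pbs"
  for (nm in c("target", "internal control", "PBS")) {
    sel <- switch(nm, target = sel_t, `internal control` = sel_i, PBS = sel_e)
    if (!any(sel)) stop("no ", nm, " samples in table")
  }
  m <- unclass(table)
  a <- rowMeans(m[, sel_t, drop = FALSE])
  b_int <- rowMeans(m[, sel_i, drop = FALSE])
  b_ext <- rowMeans(m[, sel_e, drop = FALSE])
  s_t <- rowSums(m[, sel_t, drop = FALSE] > 0)
  s_i <- rowSums(m[, sel_i, drop = FALSE] > 0)
  s_e <- rowSums(m[, sel_e, drop = FALSE] > 0)
  present <- (s_t + s_i + s_e) > 0
  lfc_int <- log2_fold_change(a, b_int, pseudocount)
  lfc_ext <- log2_fold_change(a, b_ext, pseudocount)
  rpa <- rep(NA_real_, nrow(m))
  rpa[present] <- relative_percentage_abundance(s_t[present], s_i[present],
                                                s_e[present])
  pass_lfc <- if (rule == "and") lfc_int >= lfc_cut & lfc_ext >= lfc_cut
              else lfc_int >= lfc_cut | lfc_ext >= lfc_cut
  out <- data.frame(taxon_id = rownames(m),
                    a_target = a, b_internal = b_int, b_external = b_ext,
                    s_target = s_t, s_internal = s_i, s_external = s_e,
                    log2fc_vs_internal = lfc_int, log2fc_vs_external = lfc_ext,
                    rpa = rpa,
                    enriched = present & pass_lfc & !is.na(rpa) &
                      rpa >= rpa_cut,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$rpa), -Inf, out$rpa),
                   -out$log2fc_vs_internal), ]
  rownames(out) <- NULL
  out
}

#' Overlap between sequenced and cultured genera
#'
#' Harmonizes genus names (lower-casing and stripping of strain/species
#' suffixes after the first word, plus an optional synonym map) and reports,
#' globally and per tissue, how many cultured genera were also detected by
#' sequencing.
#'
#' @param sequenced_genera named list: tissue -> character vector of genera
#'   detected by sequencing.
#' @param cultured_genera named list: tissue -> character vector of genera
#'   identified by culture.
#' @param synonyms optional named character vector mapping alternative names
#'   to canonical ones (applied after harmonization).
#' @return list: `overlap_count`, `cultured_count`, `overlap_genera`,
#'   `per_tissue` (data.frame `tissue`, `cultured`, `overlap`).
#' @export
culture_overlap <- function(sequenced_genera, cultured_genera,
                            synonyms = NULL) {
  harmon <- function(x) {
    x <- tolower(trimws(x))
    x <- vapply(strsplit(x, "[ _]"), `[`, "", 1L)
    if (!is.null(synonyms)) {
      hit <- x %in% names(synonyms)
      x[hit] <- unname(synonyms[x[hit]])
    }
    unique(x[nzchar(x)])
  }
  seq_all <- harmon(unlist(sequenced_genera))
  cult_all <- harmon(unlist(cultured_genera))
  tissues <- union(names(sequenced_genera), names(cultured_genera))
  per_tissue <- do.call(rbind, lapply(tissues, function(ts) {
    cu <- harmon(cultured_genera[[ts]])
    sq <- harmon(sequenced_genera[[ts]])
    data.frame(tissue = ts, cultured = length(cu),
               overlap = length(intersect(cu, sq)),
               stringsAsFactors = FALSE)
  }))
  list(overlap_count = length(intersect(cult_all, seq_all)),
       cultured_count = length(cult_all),
       overlap_genera = sort(intersect(cult_all, seq_all)),
       per_tissue = per_tissue)
}
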