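#' Construct an OTU count table
#'
#' The central container of the package: a numeric taxa-by-samples matrix of
#' nonnegative abundances. Counts are integers up to the rarefaction stage;
#' averaging rarefaction replicates yields real-valued tables, which are
#' equally valid members of the class.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; all
#'   entries must be finite and `>= 0`.
#' @param taxon_ids,sample_ids character vectors of unique identifiers; taken
#'   from `dimnames(counts)` when omitted.
#' @return An object of class `lb_otu_table` (a named numeric matrix).
#' @export
otu_table <- function(counts, taxon_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(taxon_ids))
    taxon_ids <- if (nrow(counts) == 0) character(0) else
      stop("taxon identifiers are required")
  if (is.null(sample_ids))
    sample_ids <- if (ncol(counts) == 0) character(0) else
      stop("sample identifiers are required")
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxon_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (any(!is.finite(counts))) stop("counts must all be finite")
  if (any(counts < 0)) stop("counts must all be >= 0")
  dimnames(counts) <- list(taxon_ids, sample_ids)
  class(counts) <- c("lb_otu_table", "matrix", "array")
  counts
}

#' @export
print.lb_otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples (total reads %s)\n",
              nrow(x), ncol(x), format(sum(x))))
  invisible(x)
}

is_otu_table <- function(x) inherits(x, "lb_otu_table")

#' @rdname otu_table
#' @param x object to coerce / test.
#' @export
as_otu_table <- function(x) {
  if (is_otu_table(x)) return(x)
  otu_table(as.matrix(x))
}

stopifnot_integer_counts <- function(table, what) {
  if (any(abs(table - round(table)) > 1e-9))
    stop(what, " requires integer counts (apply it before rarefaction averaging)")
}

#' Allowed sample classes and organs
#'
#' The controlled vocabularies for sample metadata: sample classes follow the
#' four negative-control categories of a stringently controlled low-biomass
#' survey (buffer, reagent, environment and operator controls) plus the fetal
#' tissue samples themselves; organ labels cover the profiled fetal organs.
#'
#' @format Character vectors.
#' @export
sample_classes <- c("fetal_tissue", "pbs", "reagent", "environment", "operator")

#' @rdname sample_classes
#' @export
organ_levels <- c("gut", "skin", "lung", "thymus", "spleen", "placenta",
                  "liver", "mln", "none")

#' Construct and validate sample metadata
#'
#' One row per sample. `organ` must be a real organ for fetal tissue samples
#' and `"none"` for every control class; PBS controls intended for matched
#' analyses carry the `fetus_id` of the fetus they accompanied.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param sample_class one of [sample_classes] per sample.
#' @param organ one of [organ_levels]; defaults to `"none"`.
#' @param fetus_id fetus identifier or `NA`.
#' @param ega_weeks estimated gestational age in weeks (`>= 0`) or `NA`.
#' @param facility free-form site tag.
#' @return A `data.frame` of class `lb_metadata`.
#' @export
sample_metadata <- function(sample_id, sample_class, organ = "none",
                            fetus_id = NA_character_, ega_weeks = NA_real_,
                            facility = NA_character_) {
  md <- data.frame(
    sample_id = as.character(sample_id),
    sample_class = as.character(sample_class),
    organ = as.character(organ),
    fetus_id = as.character(fetus_id),
    ega_weeks = as.numeric(ega_weeks),
    facility = as.character(facility),
    stringsAsFactors = FALSE
  )
  validate_metadata(md)
}

#' @rdname sample_metadata
#' @param md a data.frame with at least `sample_id` and `sample_class`.
#' @export
validate_metadata <- function(md) {
  req <- c("sample_id", "sample_class")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata lacks required columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("organ", "fetus_id", "ega_weeks", "facility"))
    if (is.null(md[[col]])) md[[col]] <- if (col == "organ") "none" else NA
  md$organ[is.na(md$organ)] <- "none"
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(md$sample_class), sample_classes)
  if (length(bad))
    stop("unknown sample_class ", paste(bad, collapse = ", "),
         "; allowed: ", paste(sample_classes, collapse = ", "))
  bad <- setdiff(unique(md$organ), organ_levels)
  if (length(bad))
    stop("unknown organ ", paste(bad, collapse = ", "),
         "; allowed: ", paste(organ_levels, collapse = ", "))
  fetal <- md$sample_class == "fetal_tissue"
  if (any(fetal & md$organ == "none"))
    stop("fetal_tissue samples must name an organ: ",
         paste(md$sample_id[fetal & md$organ == "none"], collapse = ", "))
  if (any(!fetal & md$organ != "none"))
    stop("control samples must have organ 'none': ",
         paste(md$sample_id[!fetal & md$organ != "none"], collapse = ", "))
  if (any(!is.na(md$ega_weeks) & md$ega_weeks < 0))
    stop("ega_weeks must be >= 0")
  md <- md[, c("sample_id", "sample_class", "organ", "fetus_id",
               "ega_weeks", "facility")]
  class(md) <- c("lb_metadata", "data.frame")
  md
}

#' Stratify samples into early / late gestational age
#'
#' Second-trimester samples are conventionally split at 16 weeks estimated
#' gestational age, with "late" defined as `>= 16` weeks.
#'
#' @param md sample metadata.
#' @param threshold week cutoff, default 16.
#' @return character vector (`"early"`, `"late"`, or `NA`) aligned to rows.
#' @export
ega_stratum <- function(md, threshold = 16) {
  ifelse(is.na(md$ega_weeks), NA_character_,
         ifelse(md$ega_weeks >= threshold, "late", "early"))
}

#' Taxonomy table with genus extraction
#'
#' Maps taxon identifiers to ranked lineage strings. Genus is taken from the
#' `g__` rank of a QIIME-style lineage (`k__...;p__...;...;g__Genus`), or from
#' the last field of a plain semicolon-separated lineage. Lineages from which
#' no genus can be parsed map to the explicit token `"unassigned"`, and such
#' taxa are excluded from genus-level screens.
#'
#' @param taxon_id character vector of identifiers.
#' @param lineage character vector of lineage strings.
#' @return A `data.frame` of class `lb_taxonomy` with columns `taxon_id`,
#'   `lineage`, `genus`.
#' @export
taxonomy_table <- function(taxon_id, lineage) {
  taxon_id <- as.character(taxon_id)
  if (anyDuplicated(taxon_id)) stop("duplicate taxon_id in taxonomy")
  if (length(lineage) != length(taxon_id))
    stop("lineage and taxon_id lengths differ")
  tx <- data.frame(taxon_id = taxon_id, lineage = as.character(lineage),
                   genus = vapply(as.character(lineage), extract_genus, ""),
                   stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  class(tx) <- c("lb_taxonomy", "data.frame")
  tx
}

extract_genus <- function(lineage) {
  if (is.na(lineage) || !nzchar(trimws(lineage))) return("unassigned")
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  gpart <- grep("^g__", parts, value = TRUE)
  if (length(gpart)) {
    g <- sub("^g__", "", gpart[length(gpart)])
    return(if (nzchar(g)) g else "unassigned")
  }
  # plain lineage: last non-empty field is the genus
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return("unassigned")
  parts[length(parts)]
}

#' Ground-truth labels for synthetic datasets
#'
#' @param taxon_id identifiers partitioning the generated taxon set.
#' @param role `"contaminant"` or `"signal"` per taxon.
#' @param target_organs list of character vectors (empty for contaminants).
#' @param mean_relative_abundance expected relative abundance in (0,1).
#' @return A `data.frame` of class `lb_truth`.
#' @export
truth_labels <- function(taxon_id, role, target_organs,
                         mean_relative_abundance) {
  role <- match.arg(role, c("contaminant", "signal"), several.ok = TRUE)
  if (any(role == "contaminant" & lengths(target_organs) > 0))
    stop("contaminants must have empty target_organs")
  tl <- data.frame(taxon_id = as.character(taxon_id), role = role,
                   mean_relative_abundance = mean_relative_abundance,
                   stringsAsFactors = FALSE)
  tl$target_organs <- target_organs
  class(tl) <- c("lb_truth", "data.frame")
  tl
}

#' Cross-check an OTU table, metadata and tree for consistency
#'
#' A pure reporting operation: it never modifies its inputs and an empty
#' report means the dataset is internally consistent. Downstream stages are
#' expected to refuse datasets with a non-empty report.
#'
#' @param table an [otu_table()].
#' @param metadata sample metadata ([sample_metadata()] / [validate_metadata()]).
#' @param tree optional rooted `phylo` tree whose tips must cover the taxa.
#' @return list with elements `samples_without_metadata`,
#'   `metadata_without_samples`, `taxa_missing_from_tree`, and logical `ok`.
#' @export
validate_dataset <- function(table, metadata, tree = NULL) {
  rep <- list(
    samples_without_metadata = setdiff(colnames(table), metadata$sample_id),
    metadata_without_samples = setdiff(metadata$sample_id, colnames(table)),
    taxa_missing_from_tree =
      if (is.null(tree)) character(0)
      else setdiff(rownames(table), tree$tip.label)
  )
  rep$ok <- all(lengths(rep[1:3]) == 0)
  rep
}
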