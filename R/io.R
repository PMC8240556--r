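#' Table dialect for delimited OTU tables
#'
#' @param delimiter single field-separator character (tab by default).
#' @param orientation `"taxa_as_rows"` (default, QIIME-era convention) or
#'   `"samples_as_rows"`.
#' @param missing token parsed as `NA` (rejected in count tables).
#' @return list of class `lb_dialect`.
#' @export
table_dialect <- function(delimiter = "\t",
                          orientation = c("taxa_as_rows", "samples_as_rows"),
                          missing = "NA") {
  if (nchar(delimiter) != 1L) stop("delimiter must be a single character")
  structure(list(delimiter = delimiter,
                 orientation = match.arg(orientation),
                 missing = missing),
            class = "lb_dialect")
}

#' Read / write OTU count tables
#'
#' Tab-delimited text with one header row of sample identifiers and one
#' leading identifier column. Malformed input (ragged rows, duplicate
#' identifiers, negative or non-numeric entries) is rejected with an error
#' naming the offending cell, never silently coerced.
#'
#' @param path file path or connection.
#' @param dialect a [table_dialect()].
#' @return [read_otu_table()] returns an [otu_table()];
#'   [write_otu_table()] returns `path` invisibly.
#' @export
read_otu_table <- function(path, dialect = table_dialect()) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty OTU table file")
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1]))
    stop("ragged rows in OTU table: row ",
         which(widths != widths[1])[1], " has ", widths[widths != widths[1]][1],
         " fields, expected ", widths[1])
  header <- fields[[1]]
  col_ids <- header[-1]
  row_ids <- vapply(fields[-1], `[`, "", 1L)
  body <- fields[-1]
  n <- length(body); m <- length(col_ids)
  mat <- matrix(NA_real_, n, m, dimnames = list(row_ids, col_ids))
  for (i in seq_len(n)) {
    cell <- body[[i]][-1]
    cell[cell == dialect$missing] <- NA
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric or missing entry at row '", row_ids[i],
           "' column '", col_ids[bad[1]], "'")
    neg <- which(val < 0)
    if (length(neg))
      stop("negative entry at row '", row_ids[i],
           "' column '", col_ids[neg[1]], "'")
    mat[i, ] <- val
  }
  if (dialect$orientation == "samples_as_rows") mat <- t(mat)
  otu_table(mat)
}

#' @rdname read_otu_table
#' @param table an [otu_table()].
#' @export
write_otu_table <- function(table, path, dialect = table_dialect()) {
  mat <- unclass(table)
  if (dialect$orientation == "samples_as_rows") mat <- t(mat)
  id_col <- if (dialect$orientation == "samples_as_rows") "sample_id" else "taxon_id"
  con <- textConnection(NULL, "w", local = TRUE)
  writeLines(paste(c(id_col, colnames(mat)), collapse = dialect$delimiter), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(rownames(mat)[i],
                       format(mat[i, ], digits = 15, trim = TRUE,
                              scientific = FALSE)),
                     collapse = dialect$delimiter), con)
  out <- textConnectionValue(con)
  close(con)
  writeLines(out, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id` and `sample_class`; `organ`, `fetus_id`,
#' `ega_weeks` and `facility` are optional. Records are validated against the
#' metadata invariants (see [validate_metadata()]).
#'
#' @param path file path or connection.
#' @return validated `lb_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!is.null(md$ega_weeks)) md$ega_weeks <- as.numeric(md$ega_weeks)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param md metadata to write.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the checks the pipeline
#' relies on: unique leaf labels, finite nonnegative branch lengths (absent
#' lengths default to 0).
#'
#' @param path file path, or a newick string via `text`.
#' @param text optional newick string (used when `path` is missing).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  tree
}

#' Read / write distance matrices as TSV
#'
#' Square labelled matrices; the reader enforces symmetry (within 1e-12) and
#' an exactly-zero diagonal, the two invariants every downstream consumer
#' assumes.
#'
#' @param path file path or connection.
#' @return [read_distance_matrix()] returns a `lb_dist` matrix.
#' @export
read_distance_matrix <- function(path) {
  mat <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  distance_matrix(mat)
}

#' @rdname read_distance_matrix
#' @param dm distance matrix to write.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm),
                   format(unclass(dm), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated distance matrix
#'
#' @param mat square numeric matrix with matching row/column names,
#'   symmetric within `1e-12`, zero diagonal, all entries `>= 0`.
#' @return matrix of class `lb_dist`.
#' @export
distance_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("distance matrix must be square")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("distance matrix must carry sample identifiers")
  if (!identical(rownames(mat), colnames(mat)))
    stop("row and column sample identifiers differ")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("distances must be finite and >= 0")
  if (max(abs(mat - t(mat))) > 1e-12)
    stop("distance matrix is not symmetric (tolerance 1e-12)")
  if (any(diag(mat) != 0))
    stop("distance matrix diagonal must be exactly 0")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  class(mat) <- c("lb_dist", "matrix", "array")
  mat
}
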