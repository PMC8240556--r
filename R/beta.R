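#' Bray-Curtis dissimilarity
#'
#' \eqn{d_{jk} = 1 - 2 \sum_i \min(c_{ij}, c_{ik}) / (\sum_i c_{ij} +
#' \sum_i c_{ik})}, computed by [vegan::vegdist()]. Values lie in `[0, 1]`.
#'
#' @param table an [otu_table()] with at least two samples, each with a
#'   positive total.
#' @return a [distance_matrix()].
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2) stop("need at least two samples")
  if (any(colSums(table) <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(table)[colSums(table) <= 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
  diag(d) <- 0
  distance_matrix(d)
}

#' Weighted UniFrac distance
#'
#' Abundance-weighted phylogenetic dissimilarity. For each branch `b` of the
#' rooted tree with length `l_b`, let `p_X(b)` be the fraction of sample X's
#' reads assigned to leaves descending through `b`. The raw distance is
#' \eqn{\sum_b l_b |p_A(b) - p_B(b)|}; the normalized variant divides by the
#' abundance-weighted root-to-leaf distance sum
#' \eqn{\sum_i d_i (p_{Ai} + p_{Bi})} (Lozupone's normalization, the
#' QIIME 1.x behaviour), giving values in `[0, 1]`.
#'
#' @param table an [otu_table()]; every taxon must be a leaf of `tree` and
#'   every sample must have a positive total.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param normalized divide by the weighted root-to-leaf sum (default
#'   `FALSE`, the raw variant).
#' @return a [distance_matrix()].
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  taxa <- rownames(table)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  totals <- colSums(table)
  if (any(totals <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(table)[totals <= 0], collapse = ", "))
  p <- sweep(unclass(table), 2, totals, "/")

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge
  elen <- tree_po$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(edge))

  # accumulate per-node leaf mass bottom-up; row = tree node, col = sample
  node_mass <- matrix(0, ntip + nnode, ncol(p))
  node_mass[match(taxa, tree$tip.label), ] <- p
  edge_mass <- matrix(0, nrow(edge), ncol(p))
  for (e in seq_len(nrow(edge))) {
    edge_mass[e, ] <- node_mass[edge[e, 2], ]
    node_mass[edge[e, 1], ] <- node_mass[edge[e, 1], ] + node_mass[edge[e, 2], ]
  }

  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (j in seq_len(n))
    d[, j] <- colSums(elen * abs(edge_mass - edge_mass[, j]))
  if (normalized) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    a <- as.numeric(t(p) %*% depth[match(taxa, tree$tip.label)])
    denom <- outer(a, a, "+")
    pos <- denom > 0
    d[pos] <- d[pos] / denom[pos]
    d[!pos] <- 0
  }
  d <- pmax(d, 0)
  diag(d) <- 0
  distance_matrix(d)
}

#' Element-wise mean of distance matrices
#'
#' Combines the per-replicate distance matrices of a rarefaction ensemble
#' into a single matrix; all inputs must share the same samples in the same
#' order.
#'
#' @param matrices list of [distance_matrix()] objects.
#' @return a [distance_matrix()].
#' @export
average_distance_matrices <- function(matrices) {
  if (!length(matrices)) stop("no matrices supplied")
  ids <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), ids))
      stop("distance matrices have mismatched sample sets")
  acc <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  distance_matrix(acc)
}

#' Beta diversity averaged over a rarefaction ensemble
#'
#' Computes the chosen dissimilarity on each rarefaction replicate and
#' averages the matrices element-wise.
#'
#' @param ensemble a [rarefaction_ensemble()].
#' @param metric `"braycurtis"` or `"wunifrac"`.
#' @param tree rooted `phylo` tree (required for weighted UniFrac).
#' @param normalized normalized weighted UniFrac flag.
#' @return a [distance_matrix()].
#' @export
beta_over_ensemble <- function(ensemble, metric = c("braycurtis", "wunifrac"),
                               tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  mats <- lapply(ensemble$tables, function(tab) {
    if (metric == "braycurtis") bray_curtis(tab)
    else {
      if (is.null(tree)) stop("weighted UniFrac requires a tree")
      weighted_unifrac(tab, tree, normalized = normalized)
    }
  })
  average_distance_matrices(mats)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centred matrix \eqn{-D^2/2}. Coordinates
#' are built from positive eigenvalues only; negative eigenvalues are
#' reported but discarded, and the proportion of variance explained is taken
#' over the positive eigenvalues.
#'
#' @param dm a [distance_matrix()] over at least two samples.
#' @param n_axes number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return list of class `lb_pcoa` with `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `proportion_explained` (per
#'   returned axis).
#' @export
pcoa_ordination <- function(dm, n_axes = NULL) {
  n <- nrow(dm)
  if (n < 2) stop("need at least two samples")
  if (!is.null(n_axes) && n_axes < 1) stop("n_axes must be >= 1")
  a <- -0.5 * unclass(dm)^2
  centred <- a - rowMeans(a)
  centred <- sweep(centred, 2, colMeans(centred))
  eg <- eigen((centred + t(centred)) / 2, symmetric = TRUE)
  eps <- max(abs(eg$values)) * 1e-9
  pos <- which(eg$values > eps)
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  axes <- pos[seq_len(k)]
  coords <- eg$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(eg$values[axes]), k, k)
  dimnames(coords) <- list(rownames(dm), paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = eg$values,
                 proportion_explained =
                   eg$values[axes] / sum(eg$values[pos])),
            class = "lb_pcoa")
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' after Anderson/McArdle: with \eqn{N} samples in \eqn{k} groups,
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' \eqn{R^2 = 1 - SS_{within}/SS_{total}}, and the pseudo-F statistic uses
#' \eqn{(k-1, N-k)} degrees of freedom. The p-value is the permutation
#' estimator \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) / (permutations + 1)};
#' exact ties count as exceedances.
#'
#' @param dm a [distance_matrix()].
#' @param grouping named character vector or factor mapping every sample of
#'   `dm` to a group label.
#' @param permutations number of random label permutations (default 999), or
#'   an integer matrix whose rows are explicit permutations of
#'   `seq_len(nrow(dm))` (e.g. exhaustive enumeration, identity included); in
#'   the latter case the p-value is the fraction of rows with
#'   \eqn{F \ge F_{obs}}.
#' @param seed integer seed for the permutation stream.
#' @return list of class `lb_permanova`: `statistic` (pseudo-F), `r2`,
#'   `p_value`, `permutations`, `df`.
#' @export
permanova <- function(dm, grouping, permutations = 999, seed = 1) {
  ids <- rownames(dm)
  if (is.null(names(grouping)) && length(grouping) == length(ids))
    names(grouping) <- ids
  labels <- grouping[ids]
  if (any(is.na(labels) | !nzchar(as.character(labels))))
    stop("unlabelled sample(s): ",
         paste(ids[is.na(labels) | !nzchar(as.character(labels))],
               collapse = ", "))
  f <- factor(as.character(labels))
  k <- nlevels(f)
  if (k < 2) stop("need at least two groups")
  n <- length(ids)
  d2 <- unclass(dm)^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  f_stat <- function(fac) {
    ind <- stats::model.matrix(~ fac - 1)
    ng <- colSums(ind)
    ss_within <- sum(colSums((d2 %*% ind) * ind) / 2 / ng)
    ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- f_stat(f)
  ss_within_obs <- {
    ind <- stats::model.matrix(~ f - 1)
    ng <- colSums(ind)
    sum(colSums((d2 %*% ind) * ind) / 2 / ng)
  }
  r2 <- 1 - ss_within_obs / ss_total

  if (is.matrix(permutations)) {
    f_perm <- apply(permutations, 1, function(idx) f_stat(f[idx]))
    p <- mean(f_perm >= f_obs)
    n_perm <- nrow(permutations)
  } else {
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(permutations),
             function(i) f_stat(f[sample.int(n)]), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs)) / (permutations + 1)
    n_perm <- permutations
  }
  structure(list(statistic = f_obs, r2 = r2, p_value = p,
                 permutations = n_perm, df = c(k - 1, n - k)),
            class = "lb_permanova")
}

#' @export
print.lb_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.5f, p = %.4g (%d permutations)\n",
              x$statistic, x$df[1], x$df[2], x$r2, x$p_value, x$permutations))
  invisible(x)
}
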