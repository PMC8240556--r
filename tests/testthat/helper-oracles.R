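# Independent brute-force oracles. Each recomputes a quantity by direct
# summation / enumeration, sharing no code path with the implementation.

oracle_shannon <- function(v, base = 2) {
  p <- v[v > 0] / sum(v)
  -sum(p * log(p, base = base))
}

oracle_chao1 <- function(v) {
  s <- sum(v > 0)
  f1 <- sum(v == 1)
  f2 <- sum(v == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_bray <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# root path of a node as the vector of child-node ids on the way up
root_path <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- integer(0)
  while (parent[node] != 0) {
    path <- c(path, node)
    node <- parent[node]
  }
  path
}

oracle_wunifrac <- function(table, tree, normalized = FALSE) {
  p <- sweep(unclass(table), 2, colSums(table), "/")
  tips <- match(rownames(table), tree$tip.label)
  paths <- lapply(tips, function(t) root_path(tree, t))
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  elen <- tree$edge.length
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- vapply(paths, function(pt) child %in% pt, TRUE)
    mass <- colSums(p[below, , drop = FALSE])
    d <- d + elen[e] * abs(outer(mass, mass, "-"))
  }
  if (normalized) {
    # root-to-tip distances by summing edge lengths along each path
    edge_of_child <- match(seq_len(max(tree$edge)), tree$edge[, 2])
    tip_depth <- vapply(paths, function(pt) sum(elen[edge_of_child[pt]]), 0)
    a <- as.numeric(t(p) %*% tip_depth)
    denom <- outer(a, a, "+")
    d <- ifelse(denom > 0, d / denom, 0)
  }
  d
}

oracle_permanova_r2 <- function(dm, labels) {
  n <- nrow(dm)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + dm[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + dm[i, j]^2
      ss_within <- ss_within + s / length(idx)
    }
  }
  1 - ss_within / ss_total
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments,
# doubling the smaller tail (capped at 1)
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  picks <- utils::combn(length(pooled), nx)
  us <- apply(picks, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
oracle_sr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# two-sided Fisher p by hypergeometric enumeration, probability-mass rule
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all permutations of seq_len(n), one per list element
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = pos)
  out
}

# random small instances -------------------------------------------------

random_count_table <- function(n_taxa, n_samples, max_count = 20) {
  mat <- matrix(sample(0:max_count, n_taxa * n_samples, replace = TRUE),
                n_taxa, n_samples,
                dimnames = list(paste0("t", seq_len(n_taxa)),
                                paste0("s", seq_len(n_samples))))
  # ensure positive totals
  for (j in which(colSums(mat) == 0)) mat[sample(n_taxa, 1), j] <- 1
  otu_table(mat)
}

random_tree <- function(taxa) {
  generate_tree(taxa, seed = sample.int(1e6, 1),
                rate = 1 / stats::runif(1, 0.5, 2))
}

euclidean_dist_matrix <- function(points) {
  d <- as.matrix(stats::dist(points))
  dimnames(d) <- list(paste0("s", seq_len(nrow(points))),
                      paste0("s", seq_len(nrow(points))))
  distance_matrix(d)
}
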