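test_that("bray-curtis matches its formula and the min-sum oracle", {
  m <- matrix(c(2, 2, 0,
                0, 2, 2,
                2, 2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  d <- bray_curtis(otu_table(m))
  expect_equal(d["s1", "s2"], 0.5)    # 1 - 2*2/8
  expect_equal(d["s1", "s3"], 0)      # identical columns
  disjoint <- otu_table(matrix(c(3, 0, 0, 5), 2, 2,
                               dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  withr::with_seed(21, {
    for (i in 1:20) {
      tab <- random_count_table(5, 4)
      d <- bray_curtis(tab)
      for (j in 1:3) for (k in (j + 1):4)
        expect_equal(d[j, k], oracle_bray(unclass(tab)[, j], unclass(tab)[, k]),
                     tolerance = 1e-12)
    }
  })
  # invariant only under scaling both columns by the same factor
  tab <- random_count_table(4, 2)
  expect_equal(bray_curtis(otu_table(unclass(tab) * 3)), bray_curtis(tab))
  expect_error(bray_curtis(otu_table(matrix(0, 1, 2,
    dimnames = list("a", c("s1", "s2"))))), "all-zero")
})

test_that("weighted unifrac reproduces closed-form small-tree values", {
  tree <- cherry_tree()
  tab <- otu_table(matrix(c(10, 0, 0, 7), 2, 2,
                          dimnames = list(c("A", "B"), c("s1", "s2"))))
  expect_equal(weighted_unifrac(tab, tree)["s1", "s2"], 2)
  expect_equal(weighted_unifrac(tab, tree, normalized = TRUE)["s1", "s2"], 1)

  # identical relative-abundance profiles -> 0 in both variants
  same <- otu_table(matrix(c(4, 6, 8, 12), 2, 2,
                           dimnames = list(c("A", "B"), c("s1", "s2"))))
  expect_equal(weighted_unifrac(same, tree)["s1", "s2"], 0)
  expect_equal(weighted_unifrac(same, tree, TRUE)["s1", "s2"], 0)

  # star topology with unit branches: raw distance is the L1 profile distance
  taxa <- paste0("t", 1:4)
  stree <- star_tree(taxa)
  tab4 <- otu_table(matrix(c(5, 3, 1, 1, 2, 2, 4, 2), 4, 2,
                           dimnames = list(taxa, c("s1", "s2"))))
  p <- sweep(unclass(tab4), 2, colSums(tab4), "/")
  expect_equal(weighted_unifrac(tab4, stree)["s1", "s2"],
               sum(abs(p[, 1] - p[, 2])))

  bad <- otu_table(matrix(1, 1, 2, dimnames = list("zzz", c("s1", "s2"))))
  expect_error(weighted_unifrac(bad, tree), "zzz")
})

test_that("weighted unifrac matches the branch-enumeration oracle", {
  withr::with_seed(31, {
    for (i in 1:25) {
      taxa <- paste0("t", 1:5)
      tree <- random_tree(taxa)
      tab <- random_count_table(5, 4)
      rownames(tab) <- taxa
      for (norm in c(FALSE, TRUE)) {
        got <- weighted_unifrac(tab, tree, normalized = norm)
        want <- oracle_wunifrac(tab, tree, normalized = norm)
        expect_equal(unclass(got), want, tolerance = 1e-9,
                     ignore_attr = TRUE)
        expect_true(all(got >= -1e-12))
        if (norm) expect_true(all(got <= 1 + 1e-12))
      }
    }
  })
})

test_that("weighted unifrac agrees with phyloseq's implementation", {
  withr::with_seed(101, {
    taxa <- paste0("t", 1:6)
    tree <- random_tree(taxa)
    tab <- random_count_table(6, 5)
    rownames(tab) <- taxa
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(unclass(tab), taxa_are_rows = TRUE),
      phyloseq::phy_tree(tree))
    for (norm in c(FALSE, TRUE)) {
      mine <- weighted_unifrac(tab, tree, normalized = norm)
      ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                         normalized = norm))
      expect_equal(unclass(mine), ref[rownames(mine), colnames(mine)],
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  })
})

test_that("distance-matrix averaging is element-wise and validated", {
  pts <- matrix(rnorm(8), 4, 2)
  d1 <- euclidean_dist_matrix(pts)
  d2 <- euclidean_dist_matrix(pts * 2)
  avg <- average_distance_matrices(list(d1, d2))
  expect_equal(unclass(avg), (unclass(d1) + unclass(d2)) / 2,
               ignore_attr = TRUE)
  expect_equal(average_distance_matrices(list(d1)), d1)
  expect_equal(average_distance_matrices(list(d1, d1)), d1)
  d3 <- d1; rownames(d3) <- colnames(d3) <- paste0("x", 1:4)
  expect_error(average_distance_matrices(list(d1, d3)), "mismatched")
})

test_that("pcoa recovers euclidean configurations", {
  # three collinear points, pairwise distances 1, 1, 2
  dm <- euclidean_dist_matrix(matrix(c(0, 1, 2), 3, 1))
  ord <- pcoa_ordination(dm)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(unclass(dm)), tolerance = 1e-9)
  expect_lt(ord$eigenvalues[2], 1e-9)
  expect_equal(sum(ord$proportion_explained), 1)

  withr::with_seed(13, {
    pts <- matrix(rnorm(30), 6, 5)
    dm <- euclidean_dist_matrix(pts)
    ord <- pcoa_ordination(dm)
    expect_equal(unname(as.matrix(dist(ord$coordinates))),
                 unname(unclass(dm)), tolerance = 1e-9)
    # eigenvalues non-increasing, proportions within [0,1]
    expect_true(all(diff(ord$eigenvalues) <= 1e-9))
    expect_true(all(ord$proportion_explained >= 0 &
                      ord$proportion_explained <= 1))
    # duplicated sample lands on identical coordinates
    dup <- rbind(pts, pts[1, ])
    dmd <- euclidean_dist_matrix(dup)
    ordd <- pcoa_ordination(dmd)
    expect_equal(ordd$coordinates[1, ], ordd$coordinates[7, ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  })
  expect_error(pcoa_ordination(dm, n_axes = 0), "n_axes")
})

test_that("pcoa agrees with classical cmdscale", {
  withr::with_seed(17, {
    pts <- matrix(rnorm(24), 6, 4)
    dm <- euclidean_dist_matrix(pts)
    ord <- pcoa_ordination(dm, n_axes = 3)
    ref <- cmdscale(unclass(dm), k = 3, eig = TRUE)
    expect_equal(abs(ord$coordinates), abs(ref$points), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(ord$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-9)
  })
})

test_that("permanova matches enumeration, adonis2, and its invariances", {
  # two tight clusters: R2 = 1
  pts <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  dm <- euclidean_dist_matrix(pts)
  g <- rep(c("a", "b"), each = 3)
  names(g) <- rownames(dm)
  expect_equal(permanova(dm, g, permutations = 19, seed = 1)$r2, 1)

  withr::with_seed(23, {
    pts <- matrix(rnorm(12), 6, 2)
    dm <- euclidean_dist_matrix(pts)
    g <- c("a", "a", "a", "b", "b", "b")
    names(g) <- rownames(dm)

    # exhaustive enumeration as oracle: identical p from the same matrix
    perms <- do.call(rbind, all_permutations(6))
    res <- permanova(dm, g, permutations = perms)
    f_all <- apply(perms, 1, function(idx) {
      r2 <- oracle_permanova_r2(unclass(dm), g[idx])
      (r2 / (2 - 1)) / ((1 - r2) / (6 - 2))
    })
    expect_equal(res$p_value, mean(f_all >= res$statistic - 1e-12))
    expect_equal(res$r2, oracle_permanova_r2(unclass(dm), g),
                 tolerance = 1e-12)

    # vegan::adonis2 cross-check of R2 and pseudo-F
    df <- data.frame(grp = g)
    ref <- vegan::adonis2(as.dist(unclass(dm)) ~ grp, data = df,
                          permutations = 5)
    expect_equal(res$r2, ref$R2[1], tolerance = 1e-9)
    expect_equal(res$statistic, ref$F[1], tolerance = 1e-9)

    # R2 invariant under global rescaling of the distances
    dm2 <- distance_matrix(unclass(dm) * 7)
    expect_equal(permanova(dm2, g, permutations = 9, seed = 2)$r2, res$r2,
                 tolerance = 1e-12)
  })
  g2 <- g; g2[1] <- NA
  expect_error(permanova(dm, g2, permutations = 9), "unlabelled")
})
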