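intensity_fixture <- function() {
  # two OTUs of genus A, one of genus B, one all-zero genus C, one unassigned
  counts <- matrix(c(
    2, 2, 0, 0, 5, 5,    # a1 (GenA)
    2, 4, 0, 0, 0, 0,    # a2 (GenA)
    0, 0, 10, 10, 4, 4,  # b1 (GenB)
    0, 0, 0, 0, 0, 0,    # c1 (GenC) -> dropped
    9, 9, 9, 9, 9, 9),   # u1 (unassigned) -> excluded
    5, 6, byrow = TRUE,
    dimnames = list(c("a1", "a2", "b1", "c1", "u1"),
                    c("g1", "g2", "s1", "s2", "p1", "p2")))
  tax <- taxonomy_table(rownames(counts),
                        c("k__B;g__GenA", "k__B;g__GenA", "k__B;g__GenB",
                          "k__B;g__GenC", "k__B;g__"))
  md <- sample_metadata(colnames(counts),
                        c("fetal_tissue", "fetal_tissue", "fetal_tissue",
                          "fetal_tissue", "pbs", "pbs"),
                        c("gut", "gut", "skin", "skin", "none", "none"),
                        c("f1", "f2", "f1", "f2", "f1", "f2"))
  list(tab = otu_table(counts), tax = tax, md = md)
}

test_that("genus intensities sum OTUs within genus then average within class", {
  fx <- intensity_fixture()
  git <- genus_mean_intensity(fx$tab, fx$tax, fx$md)
  # GenA in gut: samples (2+2, 2+4... ) column sums per genus: g1 = 4, g2 = 6
  expect_equal(git$intensity["GenA", "gut"], 5)
  expect_equal(git$intensity["GenB", "skin"], 10)
  expect_equal(git$intensity["GenA", "pbs"], 5)
  expect_false("GenC" %in% rownames(git$intensity))   # zero everywhere
  expect_false("unassigned" %in% rownames(git$intensity))
  expect_setequal(git$fetal_classes, c("gut", "skin"))
  # pooled mode collapses the fetal organs
  gitp <- genus_mean_intensity(fx$tab, fx$tax, fx$md, per_organ = FALSE)
  expect_equal(gitp$intensity["GenA", "fetal_tissue"], mean(c(4, 6, 0, 0)))
})

test_that("taxon screen applies the PBS >= fetal rule with theta band", {
  ints <- matrix(c(5, 4, 4,    # pbs
                   5, 10, 5,   # gut
                   3, 0, 2),   # skin
                 3, 3, dimnames = list(c("gA", "gB", "gC"),
                                       c("pbs", "gut", "skin")))
  git <- structure(list(intensity = ints, class_sizes = c(pbs = 2, gut = 2,
                                                          skin = 2),
                        fetal_classes = c("gut", "skin")),
                   class = "lb_intensity")
  out <- classify_enriched_taxa(git)
  lab <- setNames(out$label, out$genus)
  expect_identical(lab[["gA"]], "control_enriched")  # pbs 5 >= max fetal 5
  expect_identical(lab[["gB"]], "fetal_enriched")    # 4 < 0.5 * 10
  expect_identical(lab[["gC"]], "indeterminate")     # 4 >= 0.5 * 5
  # pbs 0 with positive fetal signal is fetal-enriched
  ints2 <- matrix(c(0, 10, 0), 1, 3,
                  dimnames = list("gD", c("pbs", "gut", "skin")))
  git2 <- git; git2$intensity <- ints2
  expect_identical(classify_enriched_taxa(git2)$label, "fetal_enriched")
})

test_that("log2 fold change handles zeros via pseudocount, antisymmetric", {
  expect_equal(log2_fold_change(8, 2, 1e-12), 2, tolerance = 1e-9)
  expect_equal(log2_fold_change(7, 7, 3), 0)
  expect_equal(log2_fold_change(8, 0, 1), log2(9))
  withr::with_seed(2, {
    for (i in 1:10) {
      a <- runif(1, 0, 50); b <- runif(1, 0, 50); pc <- runif(1, 0.1, 2)
      expect_equal(log2_fold_change(a, b, pc), -log2_fold_change(b, a, pc))
    }
  })
  expect_error(log2_fold_change(1, 1, 0), "pseudocount")
})

test_that("relative percentage abundance is the prevalence share", {
  expect_equal(relative_percentage_abundance(3, 1, 1), 60)
  expect_equal(relative_percentage_abundance(7, 0, 0), 100)
  expect_equal(relative_percentage_abundance(0, 2, 3), 0)
  expect_error(relative_percentage_abundance(0, 0, 0), "zero")
  # within [0,100], monotone in the target count
  s <- vapply(0:10, function(k) relative_percentage_abundance(k, 3, 2), 0)
  expect_true(all(s >= 0 & s <= 100))
  expect_true(all(diff(s) > 0))
})

enrich_fixture <- function() {
  ids <- c(paste0("gut", 1:3), paste0("sp", 1:3), paste0("p", 1:3))
  counts <- rbind(
    strong  = c(80, 80, 80, 0, 0, 0, 0, 0, 0),   # gut-only
    uniform = c(10, 10, 10, 10, 10, 10, 10, 10, 10),
    pbs_only = c(4, 4, 4, 4, 4, 4, 200, 200, 200),
    vs_pbs_only = c(40, 40, 40, 30, 30, 30, 1, 1, 1)) # high vs pbs, ~1 vs spleen
  colnames(counts) <- ids
  md <- sample_metadata(ids, rep(c("fetal_tissue", "fetal_tissue", "pbs"),
                                 each = 3),
                        rep(c("gut", "spleen", "none"), each = 3),
                        rep(c("f1", "f2", "f3"), 3))
  list(tab = otu_table(counts), md = md)
}

test_that("differential enrichment applies the AND rule over both controls", {
  fx <- enrich_fixture()
  out <- differential_enrichment(fx$tab, fx$md)
  row <- function(id) out[out$taxon_id == id, ]
  s <- row("strong")
  expect_equal(s$a_target, 80)
  expect_equal(s$log2fc_vs_internal, log2(81))
  expect_equal(s$log2fc_vs_external, log2(81))
  expect_equal(s$rpa, 100)
  expect_true(s$enriched)

  u <- row("uniform")
  expect_equal(u$log2fc_vs_internal, 0)
  expect_equal(u$rpa, 100 * 3 / 9)
  expect_false(u$enriched)

  v <- row("vs_pbs_only")
  expect_gt(v$log2fc_vs_external, 2)
  expect_lt(v$log2fc_vs_internal, 2)
  expect_false(v$enriched)                      # AND rule
  out_or <- differential_enrichment(fx$tab, fx$md, rule = "or")
  expect_true(out_or$enriched[out_or$taxon_id == "vs_pbs_only"])

  # sorted by RPA, then log2FC against the internal control
  expect_false(is.unsorted(rev(out$rpa)))

  # invariant to sample order
  perm <- sample(ncol(fx$tab))
  tab2 <- otu_table(unclass(fx$tab)[, perm])
  out2 <- differential_enrichment(tab2, fx$md)
  expect_equal(out2, out)

  expect_error(differential_enrichment(fx$tab, fx$md, target_organ = "lung"),
               "no target")
})

test_that("culture overlap harmonizes names and counts intersections", {
  ov <- culture_overlap(list(gut = c("GenA", "GenB", "GenC")),
                        list(gut = c("genb", "GenC sp. 1", "GenD")))
  expect_equal(ov$overlap_count, 2)
  expect_equal(ov$cultured_count, 3)
  expect_identical(ov$overlap_genera, c("genb", "genc"))
  expect_equal(ov$per_tissue$overlap, 2)

  expect_equal(culture_overlap(list(a = c("x", "y")),
                               list(a = c("z", "w")))$overlap_count, 0)
  same <- culture_overlap(list(a = c("u", "v", "w")),
                          list(a = c("w", "v", "u")))
  expect_equal(same$overlap_count, 3)
  expect_equal(same$cultured_count, 3)
  # synonym mapping
  syn <- culture_overlap(list(a = "oldname"), list(a = "newname"),
                         synonyms = c(newname = "oldname"))
  expect_equal(syn$overlap_count, 1)
})
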