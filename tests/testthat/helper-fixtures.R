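# Small in-code fixtures shared across test files.

tiny_table <- function() {
  otu_table(matrix(c(3, 0, 1, 2), 2, 2, byrow = TRUE,
                   dimnames = list(c("t1", "t2"), c("s1", "s2"))))
}

# metadata builder: organs for fetal tissues, "none" otherwise
md_quick <- function(ids, classes, organs = NULL, fetus = NULL) {
  if (is.null(organs)) organs <- ifelse(classes == "fetal_tissue", "gut", "none")
  if (is.null(fetus)) fetus <- NA_character_
  sample_metadata(ids, classes, organs, fetus)
}

cherry_tree <- function() read_newick(text = "(A:1,B:1):0;")

star_tree <- function(taxa) {
  read_newick(text = paste0("(", paste0(taxa, ":1", collapse = ","), ");"))
}

# deterministic small dataset for pipeline tests
small_sim <- function(seed = 11, ...) {
  generate_dataset(sim_config(n_fetuses = 4, seed = seed, ...))
}
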