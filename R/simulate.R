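#' Configuration for the synthetic low-biomass generator
#'
#' Defines a study layout emulating a contamination-controlled fetal-tissue
#' 16S survey: every sample (tissues and all negative controls) shares one
#' reagent-contaminant base composition — the kitome, homogeneous across
#' sample classes by construction — while fetal tissues additionally carry
#' organ-restricted signal taxa whose expected abundance falls from
#' surface-exposed organs (skin, placenta) to internal ones (thymus, spleen)
#' along an exposure-rank gradient. Counts are Dirichlet-multinomial at a
#' per-sample log-normal depth.
#'
#' @param n_fetuses number of fetuses, each contributing one sample per
#'   organ and `n_pbs_per_fetus` matched PBS buffer controls.
#' @param organs named integer vector of surface-exposure ranks (1 = most
#'   exposed). Default: skin/placenta 1, gut/lung 2, thymus/spleen 4.
#' @param n_pbs_per_fetus matched PBS controls per fetus.
#' @param n_reagent,n_environment,n_operator unmatched control counts.
#' @param n_contaminant_taxa number of kitome taxa.
#' @param contaminant_decay geometric decay of the contaminant base
#'   abundances (taxon i proportional to `contaminant_decay^i`).
#' @param n_signal_taxa number of organ-restricted signal taxa, assigned
#'   round-robin over `organs` so every organ receives a gradient dose.
#' @param signal_scale expected relative abundance of one signal taxon in a
#'   rank-1 organ.
#' @param gradient_base exposure-gradient slope: a taxon targeting an organ
#'   of rank r has expected abundance `signal_scale * gradient_base^(r-1)`.
#' @param cross_contamination fraction of each signal taxon's abundance
#'   leaking into all other samples (default 0: organ-restricted exactly).
#' @param overdispersion Dirichlet total concentration; larger is closer to
#'   multinomial. Kitome contamination is empirically homogeneous across
#'   samples, so the default is only mildly overdispersed.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters.
#' @param ega_range gestational-age range (weeks) sampled uniformly.
#' @param ct_baseline,ct_slope,ct_gain,ct_replicates,ct_replicate_sd,ct_sample_sd
#'   qPCR model: `Ct = ct_baseline - ct_slope * log10(load) + noise` with
#'   `load = 1 + ct_gain * signal_fraction`, `ct_replicates` technical
#'   replicates with noise sd `ct_replicate_sd`, and a per-sample load noise
#'   of sd `ct_sample_sd` on the log10 scale.
#' @param seed master seed; tree, compositions and count draws consume
#'   namespaced substreams of it.
#' @return list of class `lb_sim_config`.
#' @export
sim_config <- function(n_fetuses = 8,
                       organs = c(gut = 2, skin = 1, lung = 2, thymus = 4,
                                  spleen = 4, placenta = 1),
                       n_pbs_per_fetus = 1,
                       n_reagent = 3, n_environment = 3, n_operator = 2,
                       n_contaminant_taxa = 10,
                       contaminant_decay = 0.85,
                       n_signal_taxa = 12,
                       signal_scale = 0.12,
                       gradient_base = 0.85,
                       cross_contamination = 0,
                       overdispersion = 2000,
                       depth_meanlog = log(10000), depth_sdlog = 0.4,
                       ega_range = c(12, 22),
                       ct_baseline = 33, ct_slope = log2(10),
                       ct_gain = 20, ct_replicates = 2,
                       ct_replicate_sd = 0.2, ct_sample_sd = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_fetuses >= 1, n_pbs_per_fetus >= 0,
            n_reagent >= 0, n_environment >= 0, n_operator >= 0,
            n_contaminant_taxa >= 2, n_signal_taxa >= 0,
            signal_scale >= 0, gradient_base >= 0, gradient_base <= 1,
            cross_contamination >= 0, cross_contamination < 1,
            overdispersion > 0, contaminant_decay > 0, contaminant_decay <= 1)
  if (is.null(names(organs)) || any(!nzchar(names(organs))))
    stop("organs must be a named rank vector")
  bad <- setdiff(names(organs), setdiff(organ_levels, "none"))
  if (length(bad)) stop("unknown organ(s): ", paste(bad, collapse = ", "))
  if (any(organs < 1)) stop("exposure ranks must be >= 1")
  # expected composition must stay a valid mixture in the most loaded organ
  worst <- max(vapply(seq_along(organs), function(i) {
    targets <- signal_targets(cfg)
    sum(targets$abundance[targets$organ == names(organs)[i]])
  }, numeric(1)), 0)
  if (worst >= 1) stop("signal load >= 1 in some organ; lower signal_scale")
  class(cfg) <- "lb_sim_config"
  cfg
}

# round-robin assignment of signal taxa to organs with their expected
# target-organ abundance
signal_targets <- function(cfg) {
  if (cfg$n_signal_taxa == 0)
    return(data.frame(taxon_id = character(), organ = character(),
                      abundance = numeric()))
  orgs <- names(cfg$organs)[((seq_len(cfg$n_signal_taxa) - 1) %% length(cfg$organs)) + 1]
  data.frame(
    taxon_id = sprintf("signal_%02d", seq_len(cfg$n_signal_taxa)),
    organ = orgs,
    abundance = cfg$signal_scale * cfg$gradient_base^(cfg$organs[orgs] - 1),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Random rooted tree over a taxon set
#'
#' Rooted bifurcating topology from [ape::rtree()] with exponential branch
#' lengths; deterministic given the seed.
#'
#' @param taxon_ids at least two leaf labels.
#' @param seed integer seed.
#' @param rate rate of the exponential branch-length law.
#' @return an [ape::phylo] tree.
#' @export
generate_tree <- function(taxon_ids, seed, rate = 1) {
  n <- length(taxon_ids)
  if (n < 2) stop("need at least two taxa")
  withr::with_seed(seed,
    ape::rtree(n, rooted = TRUE, tip.label = taxon_ids,
               br = function(k) stats::rexp(k, rate)))
}

#' Generate a synthetic low-biomass dataset
#'
#' Draws one complete dataset under a [sim_config()]: OTU counts, sample
#' metadata (fetal tissues with fetus-matched PBS controls plus reagent,
#' environment and operator controls), a one-genus-per-OTU taxonomy, a random
#' phylogeny, and the ground-truth contaminant/signal labels. Fully
#' reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `lb_dataset` with elements `table`, `metadata`,
#'   `taxonomy`, `tree`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  cfg <- config
  subseeds <- withr::with_seed(cfg$seed,
                               sample.int(.Machine$integer.max, 3))
  contam_ids <- sprintf("contam_%02d", seq_len(cfg$n_contaminant_taxa))
  targets <- signal_targets(cfg)
  taxa <- c(contam_ids, targets$taxon_id)
  tree <- generate_tree(taxa, seed = subseeds[1])

  base <- cfg$contaminant_decay^seq_len(cfg$n_contaminant_taxa)
  base <- base / sum(base)

  # sample sheet
  fet <- sprintf("f%02d", seq_len(cfg$n_fetuses))
  rows <- list()
  for (f in fet) {
    for (org in names(cfg$organs))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste(f, org, sep = "_"), sample_class = "fetal_tissue",
        organ = org, fetus_id = f, stringsAsFactors = FALSE)
    for (k in seq_len(cfg$n_pbs_per_fetus))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0(f, "_pbs", if (cfg$n_pbs_per_fetus > 1) k else ""),
        sample_class = "pbs", organ = "none", fetus_id = f,
        stringsAsFactors = FALSE)
  }
  ctrl <- function(class, n) {
    if (n == 0) return(NULL)
    data.frame(sample_id = sprintf("%s_%02d", class, seq_len(n)),
               sample_class = class, organ = "none",
               fetus_id = NA_character_, stringsAsFactors = FALSE)
  }
  sheet <- rbind(do.call(rbind, rows), ctrl("reagent", cfg$n_reagent),
                 ctrl("environment", cfg$n_environment),
                 ctrl("operator", cfg$n_operator))
  md <- withr::with_seed(subseeds[2], {
    ega <- stats::runif(cfg$n_fetuses, cfg$ega_range[1], cfg$ega_range[2])
    names(ega) <- fet
    sample_metadata(sheet$sample_id, sheet$sample_class, sheet$organ,
                    sheet$fetus_id,
                    ega_weeks = unname(ega[sheet$fetus_id]),
                    facility = "siteA")
  })

  # expected composition per sample
  n_taxa <- length(taxa)
  comp <- matrix(0, n_taxa, nrow(md), dimnames = list(taxa, md$sample_id))
  leak <- cfg$cross_contamination
  for (j in seq_len(nrow(md))) {
    sig <- numeric(nrow(targets))
    if (nrow(targets)) {
      sig <- targets$abundance * leak
      if (md$sample_class[j] == "fetal_tissue") {
        own <- targets$organ == md$organ[j]
        sig[own] <- targets$abundance[own]
      }
    }
    s_tot <- sum(sig)
    comp[, j] <- c(base * (1 - s_tot), sig)
  }

  counts <- withr::with_seed(subseeds[3], {
    depth <- pmax(1, round(stats::rlnorm(nrow(md), cfg$depth_meanlog,
                                         cfg$depth_sdlog)))
    vapply(seq_len(nrow(md)), function(j) {
      shape <- cfg$overdispersion * comp[, j]
      g <- stats::rgamma(n_taxa, shape = shape)
      p <- if (sum(g) > 0) g / sum(g) else comp[, j]
      stats::rmultinom(1, depth[j], p)[, 1]
    }, numeric(n_taxa))
  })
  dimnames(counts) <- dimnames(comp)

  genus <- vapply(strsplit(taxa, "_"), function(x)
    paste0(toupper(substring(x[1], 1, 1)), substring(x[1], 2), x[2]), "")
  tax <- taxonomy_table(taxa, sprintf(
    "k__Bacteria;p__Synthetica;c__;o__;f__;g__%s", genus))

  truth <- truth_labels(
    taxon_id = taxa,
    role = c(rep("contaminant", length(contam_ids)),
             rep("signal", nrow(targets))),
    target_organs = c(rep(list(character(0)), length(contam_ids)),
                      as.list(targets$organ)),
    mean_relative_abundance = c(base, targets$abundance))
  truth$genus <- tax$genus[match(truth$taxon_id, tax$taxon_id)]

  structure(list(table = otu_table(counts), metadata = md, taxonomy = tax,
                 tree = tree, truth = truth, config = cfg),
            class = "lb_dataset")
}

#' Generate qPCR cycle-threshold records for a dataset
#'
#' `Ct = baseline - slope * log10(load) + noise`, where a sample's bacterial
#' load is `1 + ct_gain * s` with `s` its expected planted-signal fraction
#' (0 for all controls), plus log-normal per-sample load noise. Each sample
#' gets `ct_replicates` technical replicates. Doubling the load lowers Ct by
#' `slope * log10(2)`; with no planted signal, tissue and control Ct
#' distributions are identical in expectation.
#'
#' @param metadata sample metadata.
#' @param truth a [truth_labels()] table from [generate_dataset()].
#' @param config the dataset's [sim_config()].
#' @param seed integer seed (default: derived from `config$seed`).
#' @return data.frame with one row per replicate: `sample_id`, `replicate`,
#'   `ct`.
#' @export
generate_ct_records <- function(metadata, truth, config,
                                seed = config$seed + 101L) {
  sig <- truth[truth$role == "signal", , drop = FALSE]
  s_frac <- vapply(seq_len(nrow(metadata)), function(j) {
    if (metadata$sample_class[j] != "fetal_tissue") return(0)
    hit <- vapply(sig$target_organs,
                  function(org) metadata$organ[j] %in% org, TRUE)
    sum(sig$mean_relative_abundance[hit])
  }, numeric(1))
  withr::with_seed(seed, {
    load <- (1 + config$ct_gain * s_frac) *
      10^stats::rnorm(length(s_frac), 0, config$ct_sample_sd)
    mu <- config$ct_baseline - config$ct_slope * log10(load)
    do.call(rbind, lapply(seq_along(mu), function(j)
      data.frame(sample_id = metadata$sample_id[j],
                 replicate = seq_len(config$ct_replicates),
                 ct = mu[j] + stats::rnorm(config$ct_replicates, 0,
                                           config$ct_replicate_sd),
                 stringsAsFactors = FALSE)))
  })
}
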