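# lowbiome

Contamination-aware analysis of low-biomass 16S rRNA amplicon surveys.

## The problem

In very-low-biomass samples — fetal or placental tissue, biopsy material,
clean-room swabs — the microbial DNA contributed by extraction kits and
reagents (the *kitome*) rivals or exceeds any biological signal. Claiming an
above-background microbial presence then hinges on negative controls:
buffer (PBS) blanks processed alongside each specimen, reagent blanks,
environment and operator swabs. `lowbiome` implements the analysis layer
such a study needs, for microbiome bioinformaticians who already have an
OTU count table and want the inference, not the read processing:

* **Preprocessing** — dataset-wide singleton OTU removal, a minimum
  read-depth sample filter (default 500 reads), and repeated rarefaction
  (default 1,000 reads per sample, 10 times) with metrics averaged over the
  replicate tables.
* **Diversity** — Shannon (base 2) and bias-corrected Chao1 alpha
  diversity; Bray–Curtis and weighted UniFrac (raw and normalized) beta
  diversity; classical-scaling PCoA; one-way PERMANOVA with seeded
  permutations.
* **Contamination-aware inference** —
  * *percentile exceedance*: the 95th percentile of the PBS controls'
    Shannon indices is the background cutoff; each sample class is compared
    against PBS with Fisher's exact test on the above/below split;
  * *matched-control distances*: each tissue's distance to its
    fetus-matched PBS control, compared against the within-PBS reference
    distribution, with a within-subject normalization (each distance divided
    by the fetus mean, so organ effects are read off a common baseline of 1);
  * *qPCR summaries*: technical-replicate Ct averaging and per-organ
    comparisons against PBS and a low-signal internal-control organ;
  * *taxon screens*: genus-level mean signal intensities per sample class,
    a contaminant-vs-signal classification (PBS ≥ fetal ⇒ potential
    contaminant), and a differential enrichment statistic
    `log2FC = log2((A_i + c) / (B_i + c))` computed against an internal
    (spleen/thymus) and external (PBS) control, filtered at `log2FC ≥ 2`
    jointly with a prevalence share
    `RPA = 100 · S_target / (S_target + S_internal + S_PBS) ≥ 3%`.
* **Synthetic data** — a generator of low-biomass datasets with known
  structure: a kitome composition shared homogeneously by *every* sample
  including all controls, plus organ-restricted signal taxa whose abundance
  decays from surface-exposed organs (skin, placenta) to internal ones
  (thymus, spleen), Dirichlet-multinomial counts, per-fetus matched PBS
  blanks, and ground-truth labels for recovery testing.

## Worked example

```r
library(lowbiome)
cfg <- sim_config(seed = 42)        # default synthetic study: 8 fetuses x 6 organs
ds  <- generate_dataset(cfg)
res <- run_pipeline(ds$table, ds$metadata, ds$tree, ds$taxonomy, seed = 7)

res$permanova
#> PERMANOVA: pseudo-F = 125.7908 (df 6, 49), R2 = 0.93904, p = 0.001 (999 permutations)

res$exceedance$threshold            # 95th percentile of PBS Shannon indices
#> [1] 3.201133
res$exceedance$tests[, c("sample_class", "above", "below", "fisher_p")]
#>   sample_class above below     fisher_p
#> 1 fetal_tissue    48     0 3.449504e-08
#> 2      reagent     0     3 1.000000e+00
#> 3  environment     0     3 1.000000e+00
#> 4     operator     0     2 1.000000e+00

subset(res$enrichment, enriched,
       c(taxon_id, log2fc_vs_internal, log2fc_vs_external, rpa))
#>    taxon_id log2fc_vs_internal log2fc_vs_external rpa
#> 1 signal_07           6.695054           6.695054 100
#> 2 signal_01           6.578750           6.578750 100

table(res$taxa_screen$label)
#> control_enriched   fetal_enriched
#>               10               12
```

Reading the output: the organ grouping explains 94% of the weighted-UniFrac
variance among fetal + PBS samples; all 48 tissue samples exceed the PBS
alpha-diversity background while every reagent/environment/operator control
stays below it; the enrichment screen flags exactly the two planted
gut-restricted taxa (both fold changes ≫ 2, prevalence share 100%); and the
intensity screen labels all 10 planted kitome taxa as potential contaminants
and all 12 planted signal taxa as fetal-enriched.

A thin shell interface over the same functions lives in
`inst/scripts/lowbiome.R`:

```sh
Rscript inst/scripts/lowbiome.R simulate --seed 1 --out data/
Rscript inst/scripts/lowbiome.R run --table data/otu_table.tsv \
    --metadata data/metadata.tsv --tree data/tree.nwk --seed 1 --out report/
```

## Method notes

See the methods vignette (`vignettes/lowbiome-methods.Rmd`) for the model
assumptions, parameter defaults and their rationale, the synthetic
generator's design, numerical conventions (two-sided exact tests, percentile
interpolation, PCoA eigenvalue handling), and known limitations.
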