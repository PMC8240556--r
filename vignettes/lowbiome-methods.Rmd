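---
title: "Methods: contamination-aware analysis of low-biomass 16S surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contamination-aware analysis of low-biomass 16S surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowbiome)
```

# Setting

Low-biomass 16S surveys — fetal and placental tissue being the canonical
example — operate in a regime where reagent-borne microbial DNA (the
"kitome") is a substantial fraction of every library, including the
negative controls. The package's premise is that a claim of
above-background signal must be made *relative to matched negative
controls*, never in absolute terms. Four control classes are modelled:
fetus-matched PBS buffer blanks (the primary comparator, processed
identically to tissue from collection through sequencing), reagent blanks,
environment swabs, and operator swabs.

Analysis starts from an OTU count table; read processing, OTU picking and
taxonomy assignment are upstream concerns and out of scope.

# Preprocessing

Three fixed steps, in a fixed order:

1. **Singleton removal.** OTUs whose total count across the whole dataset
   is exactly 1 are dropped. The definition is dataset-wide, not
   per-sample: an OTU seen once in each of two samples (total 2) is kept.
   The filter requires integer counts, i.e. it runs before any averaging.
2. **Depth filter.** Samples with fewer than `min_reads` (default 500)
   total reads are dropped; a sample at exactly the threshold is kept.
3. **Repeated rarefaction.** Each retained sample is subsampled without
   replacement (multivariate hypergeometric, via `vegan::rrarefy`) to
   `depth` reads (default 1,000), `reps` times (default 10). Samples below
   the rarefaction depth are dropped; retention depends only on totals, so
   it is identical across replicates. Per-replicate seeds are drawn from
   the seeded master RNG, making the ensemble reproducible while keeping
   replicates independent.

The ordering of steps 1 and 2 is a design choice (either order is
defensible; the package fixes singletons-first and tests assert it), since
removing a singleton can push a borderline sample below the depth filter.

Diversity metrics are computed per rarefaction replicate and **the metric is
averaged** across replicates (alpha), or the distance matrices are averaged
element-wise (beta). Averaging the tables instead would destroy the integer
counts Chao1 requires and shrink the subsampling variance the ensemble is
meant to express.

# Diversity metrics

* **Shannon**: $H = -\sum_i p_i \log_2 p_i$ over positive entries. Base 2
  by default (the QIIME 1.x convention); the base is a parameter because
  published cutoff values cannot always disambiguate it.
* **Chao1** (bias-corrected): $S_{obs} + F_1(F_1 - 1) / (2(F_2 + 1))$ with
  $F_1, F_2$ the singleton/doubleton counts of the (integer) sample vector.
  The classic form is available behind a flag.
* **Bray–Curtis**: $1 - 2\sum_i \min(c_{ij}, c_{ik}) / (\sum_i c_{ij} +
  \sum_i c_{ik})$, delegated to `vegan::vegdist`.
* **Weighted UniFrac**: for each branch $b$ with length $l_b$,
  $d = \sum_b l_b\,|p_A(b) - p_B(b)|$ where $p_X(b)$ is the fraction of
  sample $X$'s reads under $b$. The normalized variant divides by the
  abundance-weighted root-to-leaf distance sum
  $\sum_i d_i\,(p_{Ai} + p_{Bi})$, bounding the value by 1. Implemented by
  a single postorder accumulation over the rooted tree; tests check it
  against an independent branch-enumeration oracle and against
  `phyloseq::UniFrac`.
* **PCoA**: eigendecomposition of the double-centred $-D^2/2$ matrix.
  Coordinates use positive eigenvalues only; negative eigenvalues (possible
  for non-Euclidean dissimilarities) are reported but discarded, and
  variance proportions are taken over the positive spectrum — the
  convention of the QIIME-era ordination stack.
* **PERMANOVA** (one-way): $SS_{total} = \sum_{i<j} d_{ij}^2/N$,
  $SS_{within} = \sum_g \sum_{i<j\in g} d_{ij}^2/n_g$,
  $R^2 = 1 - SS_{within}/SS_{total}$, pseudo-F on $(k-1, N-k)$ degrees of
  freedom, p by the $(1 + \#\{F_{perm} \ge F_{obs}\})/(\text{perms} + 1)$
  estimator with ties counted as exceedances. Implemented directly from
  these identities (cross-checked against `vegan::adonis2` in tests) so
  that permutations are cheap and exactly seed-controlled, including
  exhaustive enumeration for small samples. The pipeline runs it on the
  replicate-averaged distance matrix restricted to fetal + PBS samples,
  grouped by organ (PBS as its own group).

# Contamination-aware inference

**Percentile exceedance.** The threshold is the $q$-th percentile (default
95) of the PBS controls' Shannon values, computed by type-7 linear
interpolation. "Above" is strict (`>`); a boundary sample counts as below.
Each non-PBS class is compared to PBS by Fisher's exact test on the 2×2
above/below table, two-sided by the probability-mass rule. Because the
threshold is estimated from the same PBS samples that enter the table, the
test is conservative under the null — the synthetic null studies show
rejection rates well under nominal.

**Matched-control distances.** For each tissue sample, the mean distance to
the PBS controls sharing its fetus identifier (multiple matches are
averaged; tissues without a matched control are excluded with a warning,
never imputed). The reference set is all pairwise within-PBS distances.
Two testing modes:

* *unpaired*: per-organ Mann–Whitney U of tissue-to-matched-control
  distances against the reference;
* *paired*: distances are first normalized within fetus (each divided by
  the fetus mean, restricted to fetuses with ≥ 2 tissue records, so every
  fetus averages exactly 1), then each organ's normalized values are tested
  against 1 by Wilcoxon signed-rank. This reads the surface-to-internal
  gradient off a common baseline, independent of per-fetus differences in
  overall dissimilarity.

A pooled per-dataset variant (`matched_vs_reference_test`) divides every
tissue distance by the mean reference distance and signed-rank-tests the
ratios against 1.

**"Paired Mann–Whitney".** The paired analogue of the Mann–Whitney test is
implemented as the Wilcoxon signed-rank test — the standard choice, and the
one mainstream GUI statistics packages perform under that menu label. This
is flagged here because the naming is genuinely ambiguous; a paired
permutation of U is a defensible alternative the package does not provide.

**qPCR.** Technical replicate Ct values are averaged arithmetically into
one value per sample, exactly as stated — no amplification-efficiency
modelling. Organ classes are compared against PBS (external) and against a
designated low-signal organ, thymus by default (internal), by Mann–Whitney
U; lower Ct = more template DNA.

**Exact tests.** Mann–Whitney and signed-rank p values are exact (full
enumeration) for small tie-free samples (combined $n \le 12$, respectively
$\le 15$ nonzero differences), two-sided by doubling the smaller tail
capped at 1; otherwise the normal approximation with tie and continuity
corrections is used. Fisher's test is always exact. All three delegate to
the corresponding `stats` functions; the test suite re-derives every exact
p value by independent enumeration (assignments, sign patterns,
hypergeometric tables).

# Taxon-level screens

**Mean signal intensity** aggregates counts to genus (summing OTUs within
genus per sample; lineages with no parseable genus map to `"unassigned"`
and are excluded), then averages within each class — control classes plus
one class per fetal organ by default (a pooled fetal class is available).
Genera with zero intensity everywhere are removed.

**Contaminant-vs-signal classification.** PBS intensity ≥ the maximum
fetal intensity ⇒ `control_enriched` (the kitome signature: homogeneous
presence including blanks). PBS below $\theta \times$ the maximum fetal
intensity (with that maximum positive) ⇒ `fetal_enriched`; otherwise
`indeterminate`. The published analyses of this kind selected "top" genera
by manual curation; $\theta$ (default 0.5) replaces that curation with a
reproducible band, and results near the band should be read accordingly.

**Differential enrichment.** Per taxon, $A$ = mean normalized count in the
target organ (gut by default) and $B$ = mean in the internal control
(spleen or thymus) and in PBS. With pseudocount $c$ (default 1 normalized
count unit), $\log_2\!\big((A + c)/(B + c)\big)$; the pseudocount is
required because taxa absent from a control class ($B = 0$) are precisely
the interesting ones. Prevalence counts $S_\ast$ are "count > 0 after
preprocessing". A taxon is enriched iff both fold changes pass the cutoff
(default 2) **and** $RPA = 100\,S_t/(S_t + S_i + S_e)$ passes its cutoff
(default 3%). The AND rule over internal and external controls is the
default; an OR mode exists behind a flag. "Normalized count" defaults to
the rarefaction-ensemble average (even depth across samples); raw relative
abundances can be supplied instead, since the normalization basis of
deposited tables is not always documented.

**Culture overlap** intersects genus sets detected by sequencing with those
identified by culturing, after lower-casing, stripping of species/strain
suffixes, and an optional user-supplied synonym map.

# The synthetic generator

`sim_config()` / `generate_dataset()` emulate the structure such a study
must detect, with ground-truth labels:

* a **kitome** of `n_contaminant_taxa` (default 10) taxa with geometric
  base abundances (`contaminant_decay` 0.85, flattening the profile enough
  that even the rarest contaminant is estimable at rarefaction depth),
  shared by *every* sample — tissues and all controls — which is the
  defining homogeneity of systemic reagent contamination;
* `n_signal_taxa` (default 12) **organ-restricted signal taxa**, assigned
  round-robin over the organs (2 per organ at the defaults) with expected
  target-organ abundance `signal_scale * gradient_base^(rank - 1)`:
  exposure ranks skin/placenta 1, gut/lung 2, liver/mLN 3, thymus/spleen 4,
  so signal falls from surface-exposed to internal organs
  (`signal_scale` 0.12, `gradient_base` 0.85 → per-taxon expected
  abundances 12%, 10%, 7.4% along ranks 1/2/4). Assigning a (small) dose to
  every organ, including the internal controls, mirrors the observed
  gradual gradient rather than a binary present/absent dichotomy, and it
  is what makes tissue classes distinguishable from PBS in the intensity
  screen: the kitome share of a tissue is diluted by its signal load;
* **layout**: 8 fetuses × 6 organs, one matched PBS per fetus, 3 reagent +
  3 environment + 2 operator controls; gestational ages uniform on 12–22
  weeks;
* **noise**: Dirichlet-multinomial counts with total concentration
  `overdispersion` (default 2000). The mild default reflects the empirical
  homogeneity of kitome profiles across samples; it was chosen, together
  with the abundance scales above, from a first-principles comparison of
  class-mean sampling noise against the internal-organ dilution (the
  smallest separation the screens must resolve), and then frozen. Depths
  are log-normal (median 10,000, sdlog 0.4), so essentially all samples
  clear the 500-read filter and the 1,000-read rarefaction;
* **qPCR**: $Ct = 33 - \log_2(10)\cdot\log_{10}(\text{load}) + \epsilon$
  with load $= 1 + 20\,s$ for signal fraction $s$, log-normal per-sample
  load noise (sd 0.3 log10 units) and technical-duplicate noise (sd 0.2
  cycles) — so doubling the load lowers Ct by exactly one cycle, and a
  surface organ at $s \approx 0.2$ sits ~2.3 cycles below the blanks;
* **determinism**: one master seed; tree topology, compositions and count
  draws consume separate derived substreams.

What the generator does **not** emulate: taxonomic realism (each taxon is
its own genus), chimeras and PCR bias, cross-contamination between wells
(available as an explicit leakage knob, default 0), batch effects between
facilities, compositional correlations among taxa beyond the Dirichlet, and
read-level artefacts. Passing recovery tests therefore demonstrates that
the *inference layer* behaves correctly under the stated data-generating
model — not that real fetal-tissue data satisfy that model.

# Numerical conventions and degenerate inputs

* Distance matrices must be symmetric within $10^{-12}$ with an exactly
  zero diagonal; readers reject rather than coerce.
* Weighted UniFrac with an all-zero normalization denominator (possible
  only when all branch lengths are 0) returns 0.
* PCoA treats eigenvalues below $10^{-9}\times$ the spectral radius as
  null; duplicated samples receive identical coordinates.
* Fisher's test on a table with a zero margin returns p = 1.
* Exceedance requires ≥ 2 PBS samples; matched analyses exclude (with a
  warning) tissues lacking a matched control and fetuses with fewer than 2
  tissues; a fetus whose distances are all zero is an error, not a silent
  division by zero.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state (`withr::with_seed`).

# Validation scale

The test suite validates metrics against independent brute-force oracles on
hundreds of random small instances (≤ 6 taxa/samples, ≤ 5 leaves, to
$10^{-9}$), exact tests against exhaustive enumeration for all sample sizes
up to 10, PERMANOVA calibration over 2,000 null simulations at 99
permutations, null false-positive control over 50 signal-free datasets, and
recovery over 100 signal-bearing datasets at the default configuration —
sizes chosen to give stable rate estimates on a single CPU while exercising
the full pipeline end to end. `scripts/acceptance.R` re-runs the
single-dataset pipeline at full settings plus a 30-dataset replicate study.

# Known limitations

* The enrichment screen is not a compositional differential-abundance
  method (no ALDEx2/ANCOM-style treatment); it reproduces a deliberately
  simple fold-change-plus-prevalence rule, pseudocount included, and
  inherits that rule's sensitivity to the pseudocount at very low counts.
* PERMANOVA is one-way only; no strata, covariates or interactions.
* The exceedance test's conservatism (threshold estimated from the same
  controls) is documented but not corrected.
* No probabilistic decontamination (frequency/prevalence modelling à la
  decontam); the screens classify, they do not remove.
* Unweighted UniFrac, Jaccard, Faith's PD and rarefaction curves are out of
  scope.
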