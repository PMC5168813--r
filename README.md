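# seedmet

Links the primary-metabolite profile of dry seeds to germination vigor in
an introgression-line (IL) population. An IL panel carries single defined
wild-species chromosome segments in a common cultivated background; grown
in replicate field plots under fresh (`SDF`) and saline (`SDS`) maternal
irrigation, it lets both metabolite levels and germination behavior be
mapped to segments by comparing each IL against the recurrent control
line. `seedmet` is for researchers who have (or want to simulate) three
inputs per plot — GC-MS peak heights, seed morphology counts, and
germination plate records — and want the full chain from raw peaks to
putative QTLs, metabolite networks and vigor associations.

## What it computes

* **Relative metabolite content (RMC).** Peak heights are divided by the
  seed mass extracted, by the sample's total signal, and by the per-run-block
  median of each metabolite, giving dimensionless values with per-block
  median exactly 1; then log-transformed and completed by iterative
  low-rank (probabilistic-PCA-style) imputation.
* **Germination vigor.** Per plate: final percent; T50 (first day reaching
  half of the seeds that eventually germinated); SD-plate (standard
  deviation of per-seed germination day, a uniformity measure). Plates are
  averaged into plots; the salinity response is the SDS/SDF ratio per trait.
* **Putative QTLs.** Welch t-tests of each IL against the control line per
  condition (metabolite f-/s-QTLs, seed weight, maturation percent,
  germination traits), within-line SDS-vs-SDF tests, and fold-change QTLs
  via the log-scale interaction contrast
  (x̄IL,SDS − x̄IL,SDF) − (x̄C,SDS − x̄C,SDF). Multiplicity per scan by
  strict Bonferroni (α/n) or the permissive rule **Bcp = α/√n**.
* **Signed correlation networks.** Spearman correlations (plot level, per
  condition) filtered at FDR p < 0.05 and |r| ≥ 0.4; Walktrap communities
  on |r| weights; each community split into anti-correlated subsets by
  minimum-frustration signed bipartition (exact ≤ 15 nodes); subsets
  assembled over a signed meta-graph into two global antagonistic sets,
  **ms1** (germination-negative side) and **ms2** (germination-positive).
* **Integration.** PCA of the imputed log RMC, k-means clustering of plots
  with chi-square enrichment of germination groups
  (non / intermediate / well), and per-metabolite well-vs-non contrasts
  with linear-scale fold differences.

A synthetic-data generator (`synth_config()` / `simulate_population()`)
reproduces the assumed statistical structure — two anti-correlated latent
metabolite sets, run-block effects, planted QTLs, salinity shifts, and
germination driven by the ms2−ms1 balance — with complete ground truth, so
the whole pipeline is validated end to end without any external data.

## Worked example

Salinity fold changes from the bundled germination-trait means (per line
and condition; fold change = SDS mean / SDF mean):

```r
library(seedmet)
means <- read.delim(system.file("extdata",
                                "germination_salinity_means.tsv",
                                package = "seedmet"))
fc <- salinity_fold_change(means)
head(subset(fc, line %in% c("M82", "IL2-1-1")), 6)
#>      line    trait sdf_mean sds_mean     fc
#> 1     M82  percent    95.13    90.75 0.9540
#> 2     M82      t50     2.66     3.42 1.2857
#> 3     M82 sd_plate     1.00     1.82 1.8200
#> 7 IL2-1-1  percent    97.91   100.00 1.0213
#> 8 IL2-1-1      t50     3.00     2.50 0.8333
#> 9 IL2-1-1 sd_plate     1.41     0.93 0.6596
```

The control line germinates 4.6% less and 1.29× slower under salinity;
IL2-1-1 instead improves slightly (fc > 1 for percent, < 1 for T50) — the
signature of a salinity-tolerant germination locus.

End to end on a simulated population (730 plots × 65 metabolites):

```r
sim  <- simulate_population(synth_config(rng_seed = 1))
rmc  <- impute_missing(log_transform(normalize_peaks(sim$peaks)))
tr   <- germination_traits(sim$germination)

df   <- as.data.frame(rmc); mets <- attr(rmc, "metabolites")
sdf  <- df[df$treatment == "SDF", ]
m    <- as.matrix(sdf[, mets]); rownames(m) <- sdf$sample_id
gt   <- tr[match(sdf$sample_id, tr$sample_id),
           c("percent", "t50", "sd_plate")]
net  <- build_network(spearman_matrix(cbind(m, as.matrix(gt))))
sets <- assemble_metabolite_sets(net, walktrap_communities(net))
table(sets$sets$set[!sets$sets$is_trait])
#> ms1 ms2
#>  40  25
adjusted_rand_index(sets$sets$set[!sets$sets$is_trait],
                    sim$truth$set_assignment[
                      sets$sets$node[!sets$sets$is_trait]])
#> [1] 1
```

The two planted latent sets are recovered exactly (adjusted Rand index 1),
oriented so that ms1 holds the germination-negative metabolites. The
k-means / enrichment stage isolates the non-germinating plots:

```r
groups <- classify_germination_group(
  tr$percent[match(rownames(rmc_matrix(rmc)), tr$sample_id)])
enr <- cluster_germination_enrichment(
  kmeans_plots(rmc_matrix(rmc), k = 3, rng_seed = 1), groups)
round(enr$composition, 1)
#>        group
#> cluster  non intermediate well
#>       1 98.7          1.3  0.0
#>       2  0.0          3.4 96.6
#>       3  0.0         65.7 34.3
enr$statistic            # chi-square 1027.6 on 4 df, p = 3.8e-221
```

One cluster is essentially the non-germinating plots — the metabolic
profile alone identifies the seed batches that will not germinate.

The whole chain, including TSV artifacts and a reproducibility manifest,
runs as one call (or from a shell via `inst/scripts/seedmet-cli.R`):

```r
run_pipeline(pipeline_config(list(seed = 1, output = "seedmet_out")))
```

An externally normalized metabolite table can be supplied instead of raw
peaks via `read_rmc_table()`; the QTL scans, networks and integration then
recompute their summary statistics for that dataset. The published
field-study statistics (e.g. counts of significant comparisons, network
attribute tables, PC variances) require that study's supplementary
normalized dataset as input and are not reproducible from this repository
alone.

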