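---
title: "Methods: from seed metabolite peaks to germination vigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from seed metabolite peaks to germination vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmet)
```

## The analysis in one paragraph

`seedmet` analyses an introgression-line (IL) population: a panel of lines
that each carry one defined wild-species chromosome segment in a common
cultivated background, grown in replicate field plots under fresh (`SDF`)
and saline (`SDS`) maternal irrigation. Dry-seed GC-MS peak heights are
normalized to relative metabolite content (RMC), germination plates are
summarized into vigor traits, each IL is tested against the recurrent
control line to call putative QTLs, and the population-wide covariation of
metabolites is condensed into two antagonistic metabolite sets (ms1/ms2)
whose balance tracks germination vigor.

## Normalization model

Raw peak height for sample $s$ and metabolite $m$ is treated as

$$P_{sm} = A_{sm} \cdot w_s \cdot \ell_s \cdot b_{B(s),m},$$

where $A_{sm}$ is the biological signal, $w_s$ the seed mass extracted
(mg), $\ell_s$ a sample-level injection/derivatization load factor, and
$b_{B(s),m}$ a multiplicative run-block effect of the GC-MS batch $B(s)$.
`normalize_peaks()` inverts these nuisance factors in three ordered steps:
division by $w_s$, division by the sample's total (over non-missing
metabolites), and division by the per-block median of each metabolite. The
result is dimensionless RMC with a per-block per-metabolite median of
exactly 1 — an invariant the tests assert at machine precision. Two
consequences worth knowing:

* total-sum normalization makes the data compositional: a per-sample
  divisor that depends on all metabolites is introduced, which slightly
  couples metabolites beyond their biological correlation;
* the sample sum is computed over non-missing metabolites only, so heavily
  missing samples get a noisier divisor. The alternative (dropping
  incomplete samples) discards data and was rejected.

Values are then natural-log transformed (`log_transform()`); the base is a
pure convention since every downstream test and correlation is invariant
to it. Missing cells are completed by `impute_missing()`, an EM-style
low-rank completion: initialize with column means, repeatedly fit the
leading `n_components = 5` principal components and replace missing cells
with the reconstruction until the largest change falls below
`tol = 1e-6` (cap `max_iter = 1000`). Initialization is deterministic, so
imputation is reproducible and idempotent; observed cells are never
touched. Metabolites with more than 50% missing values are excluded from
the model and reported. Imputation feeds only the correlation, PCA and
clustering stages; all t-test scans run on non-imputed values so that
imputation error cannot manufacture significance.

## Germination traits

Each plate contributes three measures: final germination percent; T50, the
first day on which cumulative germination reaches half of the seeds that
eventually germinated (integer days, no interpolation — plate T50 values
of small integers average to the fractional plot values seen in practice);
and SD-plate, the sample standard deviation of the reconstructed per-seed
germination days, a uniformity measure. T50 is undefined for plates with
no germination and SD-plate for plates with fewer than two germinated
seeds; undefined values propagate as missing and never as zero, otherwise
plot means would be biased toward fast or uniform germination. Plates are
averaged unweighted into the field plot (the analysis unit; all plates
share the 50-seed design). The salinity response of a line is the ratio of
its SDS to SDF plot means per trait.

Vigor groups are non-germinating (exactly 0%), well-germinating (at least
95%) and intermediate. The 95% boundary is a configurable parameter of
`classify_germination_group()` because the literature uses both 94/95 and
5/95 conventions; the default follows the stricter published grouping.

## QTL calling

All scans are Welch (unequal-variance) two-sample t-tests on plot-level
values: log RMC for metabolites, raw values for morphology and
germination. Welch was chosen over the pooled t because group variances at
five replicates are unstable and the pooled test gains almost nothing when
they happen to be equal. Note that at $n = 5$ per group the Welch test is
slightly conservative (true size ≈ 0.042 at nominal 0.05); its null
calibration is exact from about $n = 10$, which is the size used by the
calibration checks.

Four contrasts are implemented:

* IL vs control within a condition (metabolite f-/s-QTLs, seed weight,
  maturation percent, germination traits);
* SDS vs SDF within a line (treatment effects);
* the fold-change QTL: the log-scale interaction contrast
  $(\bar x_{IL,SDS} - \bar x_{IL,SDF}) - (\bar x_{C,SDS} - \bar x_{C,SDF})$
  with a four-cell pooled standard error and Welch–Satterthwaite degrees
  of freedom. This is the standard estimator of a difference in fold
  changes with replicated data; testing ratios of point estimates directly
  would have no proper error model.

Multiplicity is handled per scan with $n$ = the number of IL × trait
comparisons actually performed, via either strict Bonferroni
($\alpha/n$) or the permissive variant ($\alpha/\sqrt n$), the
field's compromise between family-wise control and discovery power at
small replication. The three asterisk tiers correspond to the permissive
rule at $\alpha \in \{0.05, 0.01, 0.001\}$.

## Signed correlation networks and the ms1/ms2 partition

Within one condition, Spearman rank correlations are computed between all
metabolite pairs and between metabolites and the three germination traits
at plot level (maximizing $n$), with p-values from the t approximation and
Benjamini–Hochberg FDR across all pairs. Edges require adjusted
$p < 0.05$ and $|r| \ge 0.4$; `threshold_scan()` tabulates graph measures
over candidate cutoffs so the choice can be revisited, but 0.4 is the
default. Isolated nodes are dropped.

Community detection uses Walktrap (4 steps) with $|r|$ as the edge weight
— signs are not valid random-walk weights, so they ride along as an edge
attribute — and the modularity-maximal cut. Each community is then split
by `signed_bipartition()` into two subsets such that positive edges fall
within and negative edges across subsets, minimizing $|r|$-weighted
frustration. The search is exact (full enumeration) up to 15 nodes
($2^{14}$ colorings); larger communities use a deterministic multi-start
local search (spectral seed of the signed adjacency plus LCG-generated
restarts, single-move descent) that the tests hold to the exact optimum on
random graphs of up to 12 nodes. Weighting frustration by $|r|$ lets
strong correlations dominate conflicts; an unweighted count is available
by flag.

The global sets are assembled on a signed meta-graph whose nodes are the
community subsets and whose meta-edges aggregate all between-subset
correlations (weight = sum of $|r|$, sign = sign of the signed sum); a
second frustration minimization 2-colors it. Orientation is anchored to
germination: the side holding the majority ($|r|$-weighted) of metabolites
negatively correlated with germination percent (or positively with T50 /
SD-plate) is labelled ms1. With no germination edges the labelling is
arbitrary and flagged as such.

## Integration

PCA runs on the centered, unit-scaled, imputed log RMC matrix (metabolite
variances are heterogeneous; center-only is available). Component signs
are fixed by making each component's largest-magnitude loading positive.
K-means uses Euclidean distance, $k = 3$ by default with 50 restarts and a
fixed seed; the restarts make the optimum stable so the fixed seed is a
formality. Cluster-by-group enrichment is a Pearson chi-square without
continuity correction on the $k \times g$ contingency table, with a
warning when any expected count falls below 1. Group contrasts (well vs
non) are Welch tests on the log scale, marked by the permissive Bonferroni
rule over the number of metabolites, with fold differences reported on the
back-transformed linear RMC scale in both directions.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` describes a two-season-free caricature of the field
study: 72 ILs + 1 control, 5 plots per line × treatment, 65 metabolites.
Metabolite log-levels follow a multivariate normal with a two-set
correlation structure (`rho_within = 0.6` inside the latent sets S1/S2 of
sizes 40/25, `rho_between = -0.4` across, residual SD
`noise_sigma = 0.15`), plus sparse line-specific QTL shifts (±0.5 log
units on 3 metabolites in 20% of ILs), sparse line-specific salinity
shifts, per-(metabolite, block) run factors (`block_sigma = 0.3`,
round-robin block assignment), sample load factors, seed-mass scaling, and
2% MCAR missingness. Germination is driven by the plot balance score
(mean S2 minus mean S1 latent) through a logistic per-seed model
(`germ_beta0 = 3.3`, `germ_beta = 4`) and a shifted negative-binomial day
distribution on days 1–14 whose mean decreases with the score — chosen to
give integer-day counts and plate T50 in the 2–8 day range.

Ten percent of plots receive a metabolic failure shift (+1.5 log units on
S1, −1.5 on S2), modelling seed batches ruined between harvest and assay:
their balance collapses and they germinate at or near 0%. The intercept
and shift were set so the default population's group composition matches
the field observation of roughly one in ten non-germinating and half
well-germinating plots. Seed weight is a line-level trait with optional
weight QTLs (±0.5 mg) and no treatment effect; abortion probability rises
by 0.2 under SDS so bulked maturation percent drops by construction.

All randomness flows from one master seed through named substreams (one
per component), so regenerating a single component never perturbs the
others and regeneration is bit-identical. The ground truth — set
assignment, every planted effect, balance scores, failure flags — is
serialized with each dataset.

What the generator does not emulate: chromatograms or annotation errors,
genetic linkage between lines (ILs are exchangeable), season-level
agronomy, non-MCAR missingness (the instrument tends to censor low
abundances, which MCAR ignores — the weakest defensible assumption given
no stated mechanism), and compositional closure beyond what total-sum
normalization itself induces. Passing recovery tests therefore show that
the pipeline inverts its own assumed structure, not that real data meet
those assumptions.

## Problem sizes, determinism, degenerate inputs

The bundled checks use: full-size populations (730 plots × 65 metabolites)
for ten seeds in the end-to-end recovery; 1,000 random plates against
per-seed brute force; 1,000 random inputs against the reference Welch and
BH implementations at 1e-10; 10,000-replicate null calibration at 10 plots
per group; and 100 random signed graphs of up to 12 nodes against
exhaustive minimum-frustration search. Degenerate inputs are defined
throughout: zero-variance groups with equal means give $p = 1$; constant
columns are excluded from correlation with a report; empty plates yield
undefined T50/SD; an all-positive community bipartitions into one subset
with frustration 0; perfectly correlated (singular) generator targets are
sampled through an eigenvalue square root, while genuinely infeasible
correlation targets are rejected.

## Known limitations

Sensitivity of the metabolite-QTL scan at five replicates is modest for
0.5-log-unit effects under family-wise correction over thousands of
comparisons — a power ceiling of the design, not of the implementation:
the same scan recovers 0.8-log-unit effects reliably, and the
seed-weight QTLs (effect-to-noise 5:1) essentially always. Plots affected
by metabolic failure inflate within-line variance and further depress
metabolite-QTL power; they are kept in the scans because nothing in the
plot metadata identifies them a priori. The ms1/ms2 construction assumes
an approximately balanced signed structure; on data without it the
frustration numbers reported alongside the sets are the diagnostic to
watch.
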