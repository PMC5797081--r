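---
title: "Methods: differential methylation clusters from MeDIP-seq counts"
author: "methclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation clusters from MeDIP-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

MeDIP-seq (methylated-DNA immunoprecipitation sequencing) measures DNA
methylation indirectly: reads pile up over methylated fragments, peaks are
called per sample, peaks are merged across samples into a common set of
regions, and the read count of each region in each sample proxies its
methylation level. `methclust` implements the downstream arm of such a
study in two designs:

* a **discordant monozygotic twin design** — MZD pairs in which one twin
  responds emotionally to a CO~2~ inhalation challenge and the co-twin
  does not, with MZC (concordant non-responder) pairs as controls; and
* a **two-group animal design** — mice exposed to repeated cross-fostering
  (RCF) versus normally reared controls (CT), in two generations, with
  libraries immunoprecipitated in shared pools.

Downstream of the differential tests, the package clusters methylated
regions along the genome, annotates the clusters, runs a
cluster-debiased Gene Ontology enrichment, profiles clusters against
chromatin-state tracks, and measures cross-assembly conservation of
clusters.

# Models and procedures

## Normalization

Between-library scaling uses the trimmed mean of M-values (TMM). The
reference library is the one whose 75th-percentile count-per-library-size
is closest to the mean of those percentiles. For every library, M-values
(log2 count ratios against the reference) and A-values (average log2
abundances) are formed over regions positive in both libraries, doubly
trimmed (30% on M, 5% on A), and combined by a precision-weighted mean;
factors are rescaled to geometric mean 1 and multiply the library sizes
into *effective* library sizes. CPM (counts per million) is always
computed against effective library sizes. The implementation is written
here and is checked in the test suite against an independent reference
implementation (edgeR's), to which it agrees to numerical precision;
edgeR is never called by the analysis code itself.

## Twin DMR testing

Within each MZD pair, the per-region log2 fold change is
`log2((cpm_responder + pc) / (cpm_nonresponder + pc))`, where the
pseudocount `pc` is 0.5 raw counts rescaled to each sample's CPM units
(0.5 is a conventional guard against zeros; the analysis is insensitive
to it at the count depths simulated). Across the MZD pairs an
intercept-only linear model — a one-sample t-test of mean logFC ≠ 0 —
is fitted per region, two-sided. With `moderation = "on"` (the default)
region variances are shrunk toward a common prior fitted by the standard
empirical-Bayes moment estimator on log sample variances (prior degrees
of freedom from the inverse-trigamma equation; the posterior variance
enters a t-statistic with prior + residual df). The moderated mode
mirrors the behaviour of lmFit/eBayes-style analyses and agrees with
limma to 1e-8 in the tests; the plain mode is retained because the exact
published choice is not recoverable, and because the unmoderated test is
the one with textbook null calibration. Regions at p < 0.001 are DMRs.

DMRs are then passed to a second stage: the nine MZD |logFC| values are
compared against the nine MZC |logFC| values by a one-tailed Wilcoxon
rank-sum test (MZD stochastically greater), exact when both sides have at
most 12 values and no ties, otherwise normal approximation with tie and
continuity correction. MZC member order within a pair is fixed
lexicographically; only the absolute value is consumed, so the choice is
immaterial. Regions with Wilcoxon p < 0.05 are retained.

A property worth knowing: on completely null data the *first* stage is
calibrated (fraction of p < 0.001 within Monte-Carlo error of 0.001),
but the *second* stage is mildly anticonservative, because the regions it
tests were selected for extreme MZD statistics, which biases their MZD
|logFC| upward relative to MZC. At the simulated study conditions the
null retention ranges roughly 0.05–0.2 across seeds around the nominal
0.05. This is a structural property of the staged design, not an
implementation artifact, and it is visible in the calibration quantities
the acceptance script reports.

## Animal DMR testing

Regions are first filtered to those with CPM > 1 in at least 5 samples
(the size of the smallest experimental group). Each retained region is
fitted with a log-link negative binomial GLM: design
`~ group + ip_pool`, offsets `log(effective library size)`. A single
common dispersion α (variance function `μ + αμ²`) is estimated across
regions by method of moments on Pearson residuals — the α at which the
summed Pearson statistic of per-region Poisson mean fits equals its
residual degrees of freedom, floored at 0 (the Poisson limit). The group
effect is tested by the likelihood-ratio χ²(1) of the full model against
the pool-only model; IRLS runs at tolerance 1e-8, at most 100
iterations, and non-converged regions are flagged and excluded from the
significant set. One common dispersion (rather than per-region or
trended) is the simplest defensible choice given that no dispersion
model is prescribed for the analysis being reproduced; the GLM fitting
itself is delegated to `stats::glm.fit` with a fixed-θ negative binomial
family.

## Methylation clusters and ccDMRs

Regions are clustered per chromosome by DBSCAN with ε = 10 000 bp and
minimum neighbourhood size 2. The inter-region distance is the *gap*
distance (`max(0, max(starts) − min(ends))`, 0 for overlapping regions):
region lengths vary, and a 10-kb radius reads naturally as a genomic
gap; a midpoint distance is available for sensitivity analysis. The ε
comparison is inclusive (`d ≤ ε`), the common DBSCAN convention. With
minPts = 2 the core/border distinction collapses and the result equals
the connected components of the ε-gap graph, which removes DBSCAN's
order dependence; the implementation is validated against a brute-force
component oracle on 1000 random instances. Isolated regions are noise
and never enter cluster-level analyses (they can still be DMRs at the
region level). A cluster containing at least one DMR at p < 0.001 is a
ccDMR; cluster size is the span from the first member's start to the
last member's end.

## Cluster-debiased GO enrichment

Clusters are annotated with genes overlapping the span or within 100 kb
on either side (the scale of chromatin contact domains). The background
gene set is every gene associated with *any* cluster. Because genes in
one cluster can be functionally related, a single hypergeometric test on
all annotated genes is biased; instead one gene is drawn uniformly from
each cluster, the upper-tail hypergeometric test
`P(X ≥ k)` is run on that selection, terms are ranked by ascending p
(ties: descending overlap, then term id), and over 100 such
randomizations each term is scored by the geometric mean of its ranks
(lower is better). Terms absent from a run receive rank
(number tested + 1).

The published description of the empirical p ("shuffling of the
scores") does not specify the null; the declared interpretation here is
a background resampling: in each of B repetitions every cluster's gene
set is replaced by a size-matched uniform draw from the background and
the full geometric-mean-rank scoring is replayed. Replaying the
procedure exactly makes observed and null scores exchangeable under the
null, so `p = (1 + #{null ≤ observed})/(B + 1)` is uniform on its
attainable grid — a property the test suite checks. The grid is only as
fine as the term set is rich; with very few terms the p-values are
visibly discrete and conservative. GO ancestry propagation is *not*
performed (the map is used as given; the synthetic maps are flat) — real
GO usage would require propagating annotations up the DAG first. The
export for semantic-similarity visualization applies the stated filters
(hypergeometric p < 0.01, term size > 1 and < 50 within the background,
top 50 per ontology) and writes term id and ranking score.

## Feature and chromatin-state enrichment

DMR enrichment in a feature track (repeat classes, genomic features, CpG
islands) is, by default, a two-sided Fisher exact test on the 2×2 table
of (DMR vs non-DMR region of the tested universe) × (overlaps the track
vs not); the natural background is the set of all tested peak regions.
The reported odds ratio is the sample odds ratio. A placement-permutation
mode (random draws of equally many regions from the universe) is provided
as an alternative; both are labelled in the output, since the exact
statistic of the reproduced analysis is described only in supplementary
material that is not available.

Per-cluster chromatin-state profiles z-score the observed overlap
fraction of each cluster with each (tissue, state) track against random
placements of a length-matched interval on the same chromosome (the
null preserves chromosome and length but not sequence context — a
documented simplification). The null standard deviation is floored at
machine ε, giving z = 0 for constant nulls. Each cluster is assigned to
the tissue with the largest sum of z over the activation states
(defaults: active TSS, flanking TSS, strong transcription, genic
enhancers, enhancers of the common 15-state model — the reproduced
analysis does not enumerate its activation subset); ties fall to the
first tissue in sorted order and are flagged. Clusters are grouped by
average-linkage hierarchical clustering of their z-profiles, cut at k =
4 groups (k is exposed).

## Cross-species conservation

Human cluster spans are mapped to mouse coordinates through a simplified
chain: ungapped, co-linear, strand-preserving blocks of equal source and
destination length. A region maps when at least `minMatch` = 0.1 of its
bases are covered by blocks (the UCSC liftOver semantics, measured on
the source bases); the destination interval is the hull of the images,
required to land on a single destination chromosome (otherwise
"split"). Real liftOver output can be supplied as a pre-mapped BED to
skip this step. Conserved regions are ≥ 1-bp intersections between
mapped human clusters and native mouse ccDMRs; one human cluster hitting
two mouse clusters yields two conserved regions but one human cluster
hit. The significance of the conserved count is a placement permutation:
each mapped cluster is relocated uniformly on its chromosome (length
preserved) B times, and `p = (1 + #{null ≥ observed})/(B + 1)`,
one-sided for excess overlap. The published analysis prints a p-value
for this count without describing its null; the permutation here is an
explicit substitute, not a reconstruction.

# The synthetic-data generator

No sequencing data are distributed with the study being emulated, so the
generator is the package's test bed. It emulates:

* **Design:** 9 MZD + 9 MZC twin pairs; mouse groups of 6 CT / 10 RCF
  (F0) and 5 CT / 7 RCF (F1); 6 immunoprecipitation pools assigned
  round-robin (the real pooling scheme is not fully specified; the
  published account pools 8 randomly selected libraries per reaction).
* **Counts:** negative binomial with `var = μ + αμ²`, a single global
  α = 0.1; region baselines Gamma-distributed around `baseline_mean`
  = 50 expected counts; library-size factors log-normal with CV 0.2; a
  shared log-normal pair effect (sd 0.25 log2 units) for twins, so pair
  effects cancel in within-pair logFCs; a per-pool, per-region
  log-normal batch effect (sd 0.15 log2) for mice, which is what makes
  the pool covariate matter.
* **Planted signal:** 60 clusters of 4 DMR peaks each (1.2% of the
  default 20 000 regions — a typical planted fraction for benchmarking
  recovery), consecutive planted peaks separated by < 10 kb and planted
  clusters separated from background peaks by gaps strictly greater
  than 10 kb. The strict inequality matters: the clustering radius is
  inclusive at 10 000 bp, so a flanking gap of exactly 10 kb would merge
  a background peak into a planted cluster and the planted spans would
  no longer be exactly recoverable. Planted effects have magnitude
  `effect_log2fc` (default 1.5) with 81% positive (hypermethylated in
  responders/RCF), mirroring the direction imbalance of the emulated
  study. MZC pairs are a true null: both members share expected values.
* **Annotation:** a flat GO map with one planted term whose genes are
  placed one per planted cluster within the 100-kb annotation window;
  random repeat/feature tracks; a 12-tissue × 15-state chromatin track
  grid in which the planted tissue's activation states additionally
  cover the planted spans; and a monotone block map covering half of the
  genome, paired with a destination genome 1.5× longer.

What the generator does **not** emulate: CpG density and sequence
context, fragment-level immunoprecipitation chemistry, correlated
repeat/GC structure in tracks, GO DAG structure, and cell-composition
heterogeneity of whole blood. Passing tests therefore demonstrate
correctness of the algorithms under the stated noise model, not
robustness to every artefact of real MeDIP-seq data.

All randomness flows from named sub-seeds derived deterministically from
one global seed; identical configurations produce byte-identical files.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere a user sees them (BED
  convention); chromosome names are matched exactly, with no "chr"
  normalization.
* Merging coalesces bookended intervals (gap 0), matching
  `bedtools merge`.
* Zero-variance regions in the twin test: p = 1 when the mean is also 0;
  otherwise an infinite statistic with the smallest representable
  positive p.
* Degenerate 2×2 tables give p = 1 and an undefined odds ratio; constant
  permutation nulls give z = 0 (state profiles) or p = 1 with a log line.
* GLM dispersion is floored at 0 and the family degrades to Poisson;
  non-converged regions are excluded from significance calls, never
  silently kept.
* Tie-breaks are always deterministic and documented: term ranking
  (p, then −k, then id), tissue assignment (sorted tissue order),
  MZC member order (lexicographic sample id), cluster ids
  (chromosome, then leftmost start).

# Problem sizes used by the tests and the acceptance script

The validation suite exercises: the clustering oracle on 1000 random
instances of up to 200 regions; exact-test enumeration up to universes
of 12 (hypergeometric) and 8-vs-8 (rank-sum); null calibration on a
100 000-region twin study; parameter recovery on the 20 000-region twin
default and a 6 000-region mouse study at baseline 100 and log2 effect
2; GO scoring with 100 randomizations and a 200-repetition empirical
null; conservation with B = 999 for the planted configuration and 200
replicates at B = 199 for null uniformity; and 50 random matrices for
the TMM reference comparison. These sizes keep the full validation
inside a few minutes on one core while leaving every Monte-Carlo band
much narrower than the effects being detected. The heavier generator
settings used in calibration runs disable the track grid (1 tissue × 1
state), which no calibration quantity consumes.

# Known limitations

* The empirical-p null for GO scores and the conservation p-value are
  declared interpretations of under-specified procedures (see above);
  both are calibrated by construction and by test, but neither is a
  reconstruction of the original computation.
* The Wilcoxon stage's null retention is anticonservative after
  first-stage selection (see "Twin DMR testing").
* Common (not tagwise/trended) NB dispersion; no quasi-likelihood tests.
* No cell-composition correction — no MeDIP-seq reference epigenome for
  blood cell populations exists to support one.
* The simplified chain model does not parse real UCSC chain files;
  pre-mapped BED output of real liftOver is the supported route for real
  data.
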