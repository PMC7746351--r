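---
title: "Characterizing the tumor microenvironment from bulk tumor profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the tumor microenvironment from bulk tumor profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bulk tumor molecular profiles mix malignant cells with infiltrating immune
and stromal cells. The composition of that mixture — the tumor
microenvironment (TME) — carries prognostic information and is a candidate
biomarker for immunotherapy response. `tmescore` implements a complete
workflow for quantifying it: estimate immune cell-type fractions from bulk
expression, group samples into infiltration patterns, derive a prognostic
per-sample **TME score** from the genes those patterns differentially
express, dichotomize it at a data-driven cutpoint, and relate the resulting
groups to survival, pathway enrichment, mutational processes and copy-number
aberrations.

Every stage can be exercised without external data through a synthetic
cohort generator that plants known infiltration patterns, survival effects,
mutational signatures and copy-number events, so each stage's output can be
compared against ground truth.

# Models and procedures, stage by stage

## Cell-type deconvolution

`deconvolve()` estimates fractions of 22 leukocyte subsets by linear-kernel
nu-support-vector regression of each (linear-scale) mixture column on a
cell-type signature matrix, the approach popularized by CIBERSORT. The
signature matrix is standardized jointly (one mean and SD over all its
entries, computed on the genes shared with the mixture) and each mixture
column by its own mean and SD on the same genes. The SVR is fit at
nu in {0.25, 0.5, 0.75}; the nu minimizing the RMSE between the refitted
mixture and the observed one wins; negative coefficients are clipped to
zero and the rest renormalized to the simplex. The permutation p-value
compares each sample's fit correlation to a shared null built from
gene-shuffled mixtures (1,000 permutations by default).

Assumptions worth knowing: the mixture must be on a linear scale (a
`max < 50` heuristic warns about log-scale input), and quantile
normalization is off by default, as is recommended for RNA-seq. Degenerate
fits (all coefficients non-positive) return uniform fractions and are
flagged rather than erroring, so cohort-level runs never die on one sample.
The packaged 22-type reference (`synthetic_lm22()`) is a synthetic
block-structured stand-in — 20 marker genes per cell type at roughly
30-fold contrast — not the real LM22 file; a real signature matrix can be
supplied via `read_signature_matrix()`.

## Consensus clustering and the choice of K

`consensus_cluster()` follows the Monti resampling scheme: subsample 80% of
items, cluster with k-means (k-means++ seeding, Lloyd iterations, 10
restarts — a hierarchical Ward base is available), and record for every
item pair the fraction of co-samples in which they co-clustered. The
consensus CDF is integrated over [0, 1] for each K; `select_k()` picks the
largest K whose relative area gain over K−1 exceeds 0.1, defaulting to the
smallest K when no elbow exists. The package the original workflow wrapped
leaves K to the analyst's eye; a deterministic rule is needed for a tested
pipeline, and all Δ-areas are returned so an analyst can override.

## Differential expression

Counts are filtered (`filter_low_expression()`: at least 10 in at least 20%
of samples, both bounds inclusive) and transformed to
`log2((count + 0.5) / (libsize + 1) * 1e6)` (`voom_transform()`; precision
weights from a lowess mean–variance trend are available but off by
default). `moderated_t()` shrinks each gene's pooled two-group variance
toward a prior estimated by method of moments on the log residual
variances — the empirical-Bayes moderated t — and applies the significance
rule `p < 1e-3` and `|log2FC| > 1`. Forcing the prior degrees of freedom to
0 recovers the ordinary pooled t exactly, and to infinity a z-like test;
both limits are asserted in the tests, and the estimates are cross-checked
against limma on fixtures. Because three pairwise contrasts cannot yield a
three-way intersection larger than their minimum, "common" DEGs are defined
as significant in at least 2 of 3 contrasts (configurable).

## The TME score

`rf_reduce()` trains a random-forest classifier of cluster membership and
keeps genes whose permutation importance exceeds the mean — a
dimension-reduction step, not a calibrated test. The retained signature
genes are themselves consensus-clustered into gene clusters
(`cluster_genes()`); each cluster's per-sample score is its PC1 projection
after z-scoring genes (`score_gene_clusters()`), with the PC1 sign fixed so
the loading sum is non-negative — PC signs are otherwise arbitrary and
would flip between runs. A univariate Cox fit of survival on each cluster
score labels it favourable (HR < 1) or unfavourable, and

> TME score = sum(favourable cluster scores) − sum(unfavourable cluster scores).

The dichotomizing cutpoint is the maximally selected standardized log-rank
statistic (`maxstat_cutpoint()`): every observed score inside the 10–90%
quantile range is a candidate split, and the one with the largest absolute
standardized log-rank statistic wins (ties to the smaller value). Because
the maximum over many correlated splits has no convenient null, the p-value
permutes scores against (time, event) pairs, which is assumption-free and
seedable.

## Survival statistics

Kaplan–Meier curves, log-rank tests and Cox models are delegated to the
`survival` package with Breslow tie handling (simpler than Efron;
differences are negligible at these scales). The classical identity that
the Cox score test for a two-group covariate equals the log-rank chi-square
is asserted to 1e-6 in the tests. The cell interaction network scores each
cell type's survival impact as −log10 of the log-rank p at a median
abundance split, signed by which side fares worse, with Spearman
correlation edges (|rho| ≥ 0.2, p < 0.05 by default). ROC/AUC and the
DeLong paired comparison are delegated to `pROC`; the outcome column is
user-supplied (the synthetic generator emits a response flag tied to the
planted favourable pattern).

## Enrichment

`ora()` is the one-sided hypergeometric tail with BH correction over any
GMT collection — gene-ontology hierarchies are deliberately out of scope,
so there is no annotation-database version dependency. `gsea()` implements
the weighted (p = 1) running-sum enrichment score with gene-label
permutation for p and NES (phenotype permutation is a flag); the default
ranking metric is signal-to-noise with the classical 20% SD floor.

## Mutational signatures

`build_catalogue()` counts SNVs into the 96 trinucleotide categories (six
pyrimidine substitutions × 16 flank combinations), reverse-complementing
purine-reference records; contexts must be supplied in the input (no genome
FASTA handling). `extract_signatures()` is an
automatic-relevance-determination NMF: KL-divergence multiplicative updates
with half-normal priors whose per-signature relevance weights carry an
inverse-gamma(a = 10) hyperprior; signatures whose mass collapses below
1e-3 of the maximum are pruned, so the surviving count is the chosen k.
Convergence is a 1e-7 relative tolerance on the penalized objective; the
best of the random restarts (100 by default; the reference setting of
1,000 is one argument away) is kept, and a plain KL-NMF with an
elbow-based k choice is available as `method = "plain"`.

One subtlety the tests encode: an exactly factorizable catalogue with
disjoint-support signatures is *not* enough to identify the factors — the
exposure matrix must be separable (some near-pure samples per signature),
otherwise equally exact rotated factorizations exist. The recovery fixtures
therefore include pure-exposure samples, and with them the ARD-NMF recovers
the planted signatures at cosine ≈ 1.

Cosine matching reports each de-novo signature's best match in a reference;
the packaged 30-column reference (`synthetic_cosmic_reference()`) is a
synthetic COSMIC-v2-like stand-in whose first columns mimic well-known
process shapes — matches against it identify shapes, not aetiologies.
`apobec_enrichment()` implements the TCW fold-enrichment: among cytosine
mutations (C>T and C>G by default; `subs = "ct"` restricts to C>T), the
fraction at TpCpW is divided by the fraction of TCW motifs among cytosines
in the ±20 bp windows (both strands), with a one-sided Fisher test and the
conventional score > 2 enrichment call. `compute_tmb()` counts non-silent
records, raw and per 38 Mb of exome.

## Copy number

`arm_level()` calls a sample's arm gained/lost when qualifying segments
(value > 1 / < −1 under the default `"integer"` preset; ±0.1 under
`preset = "log2"` for log2-ratio segment values) cover at least half the
arm. `gscore()` bins the genome (1 Mb
default) and sums, per bin, each sample's maximal qualifying amplitude —
frequency times amplitude in one number, invariant to segment
fragmentation. True GISTIC's marker-level background model is replaced by
a cyclic-shift permutation null: each sample's genome-wide bin profile is
rotated by a random offset, preserving its event sizes and count while
destroying cross-sample alignment; empirical p-values pooled over bins and
permutations get BH correction, and peaks are maximal runs of bins under
the q threshold. This is "GISTIC-like", not GISTIC.

# The synthetic cohort generator

`sim_config()` fixes the reference study conditions; all generators are
pure functions of it (seed included):

* **Expression** — 300 samples, three infiltration patterns; cell
  fractions drawn from pattern-specific Dirichlet distributions (each
  pattern concentrates alpha = 4 on its own block of cell types over a
  0.25 baseline, so every cell type is strongly represented in exactly one
  pattern); expression is the reference mixture scaled to a log-normal
  library size (mean 2e5, CV 0.15) with negative-binomial noise at
  dispersion 0.1, a typical bulk RNA-seq value.
* **Survival** — exponential event times with pattern hazard ratios
  (0.5, 1, 2) around a 3-year baseline median, and independent exponential
  censoring whose rate is solved numerically so the expected censored
  fraction is 0.3. Exponential hazards keep a closed-form truth for Cox
  log-HR recovery.
* **Mutations** — per-sample exposures over three planted 96-context
  signatures (an APOBEC-like one with 90% of its mass on T[C>T]W/T[C>G]W,
  a CpG-deamination-like C>T-at-NpCpG one, and a broad C>A one), a
  multinomial catalogue of 50–200 SNVs per sample, fabricated positions,
  uniform random ±20 bp flanks, and half the records emitted on the purine
  strand to exercise collapsing. Positions are arbitrary; the context
  string is authoritative.
* **Copy number** — background segment values N(0, 0.1) on random
  breakpoints over a toy genome (4 chromosomes × 2 arms × 50 Mb); an arm
  gain (+1.5) planted on chr2q in 60% of samples and an arm loss (−1.5) on
  chr3p in 50%; focal events of ±2 over 1 Mb windows in 40%/30% of
  samples. Events hit an exact `round(fraction × n)` subset of samples so
  the planted fraction is exact by construction rather than a binomial
  draw.

What the generator does *not* emulate: batch effects, GC/length biases,
purity gradients (purity/ploidy enter only as optional annotation columns),
subclonal copy-number mixtures, indel/DBS signature structure, or gene-gene
correlation beyond the cell-type mixture. Passing recovery tests on this
cohort therefore demonstrates the algorithms are implemented correctly and
recover planted structure under realistic count noise — not that results on
real tumors will be as clean.

# Numerical choices and edge cases

* Seeds are mandatory wherever randomness exists; all generators and
  resampling procedures restore the caller's RNG state.
* Duplicate gene symbols on input collapse to the max-mean profile (the
  choice is logged); gene matching is exact string equality after
  upper-casing and whitespace stripping, with no alias resolution.
* Mutation/segment coordinates are 1-based inclusive throughout.
* Zero-variance genes in `moderated_t()` get the prior variance as a floor
  (p = 1 when the fold change is also zero); zero-variance fraction
  columns are dropped from network edges with a warning; consensus item
  pairs never co-sampled score 0 with a warning; k-means++ centers get a
  1e-9 jitter to break exact ties.
* The pipeline derives each stage's seed as a stable 32-bit hash of the
  stage name plus the master seed, so adding stages never perturbs
  existing ones.

# Problem sizes used by the test suite

The shipped tests run the full study conditions wherever that is cheap and
reduced sizes where it is not, as the package's own test-scale choices:
consensus clustering is tested with 100–200 resamples (the pipeline default
stays 1,000), the end-to-end score-direction check uses 20 cohorts of 100
samples, NMF recovery uses 5–10 restarts, and permutation nulls use
100–1,000 draws. The acceptance script runs the full default cohort
(n = 300) with 1,000 consensus resamples.

# Known limitations

* The deconvolution reference and the signature-matching reference are
  synthetic stand-ins; conclusions about specific cell types or mutational
  aetiologies on real data require the corresponding real reference files.
* The G-score null is a cyclic-shift permutation, not GISTIC's semi-exact
  marker model; q-values are comparable in spirit, not in value.
* `rf_reduce()`'s importance-above-mean rule is a heuristic reduction, not
  an error-controlled selection.
* The maxstat permutation p does not adjust for the quantile-range choice;
  narrow ranges inflate the statistic's ceiling.
* Consensus clustering of genes reuses the sample-clustering machinery on
  the transposed z-scored matrix; for very large DEG sets the item × item
  consensus matrices grow quadratically.
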