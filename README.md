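# tmescore

Characterize the tumor microenvironment (TME) from bulk tumor molecular
profiles, and score its prognostic impact.

Bulk tumor expression is a mixture of malignant, immune and stromal cells.
This package implements the full workflow for turning that mixture into a
prognostic biomarker:

1. **Deconvolution** — per-sample fractions of 22 leukocyte subsets by
   linear nu-SVR against a cell-type signature matrix (CIBERSORT-style),
   with permutation p-values.
2. **Infiltration patterns** — Monti resampling consensus clustering of the
   fraction matrix; the number of clusters K maximizes the relative gain in
   consensus-CDF area (elbow rule, threshold 0.1).
3. **Cluster-associated genes** — empirical-Bayes moderated t between
   clusters on voom-style log-CPM, significance rule `p < 1e-3` and
   `|log2FC| > 1`, "common" genes significant in ≥ 2 of 3 contrasts.
4. **TME score** — random-forest reduction to signature genes, consensus
   gene clusters, per-cluster PC1 scores, and

   `TME score = Σ favourable cluster scores − Σ unfavourable cluster scores`

   with directions from univariate Cox fits, dichotomized at the maximally
   selected standardized log-rank cutpoint (permutation p).
5. **Genomic context** — Kaplan–Meier/log-rank/Cox summaries, a
   tumor–immune cell interaction network, ROC comparison of the score
   against tumor mutation burden, gene-set over-representation and GSEA,
   96-context mutational catalogues with ARD-NMF signature extraction
   (half-normal priors, a = 10, tolerance 1e-7), cosine matching, APOBEC
   TCW enrichment (score > 2 rule), and GISTIC-like copy-number G-score
   peak calling.

A synthetic cohort generator (`sim_config()`, `simulate_cohort()`,
`simulate_mutations()`, `simulate_cnv()`) plants known infiltration
patterns, survival effects, mutational signatures and copy-number events so
that every stage is testable against ground truth without external data.
The bundled deconvolution and signature-matching references are synthetic
stand-ins; real reference files (e.g. LM22, COSMIC) can be supplied via
`read_signature_matrix()`.

## Worked example

```r
library(tmescore)

cfg    <- sim_config(n_samples = 120, seed = 7)        # study conditions
cohort <- simulate_cohort(cfg)

fr <- deconvolve(cohort$expression, cfg$reference, n_permutations = 0)
cc <- consensus_cluster(fr$fractions, n_resamples = 200, seed = 8)
cc
#> ConsensusResult: K in {2,3,4,5,6}, chosen K = 3 (200 resamples)
#>              2      3      4      5      6
#> CDF area 0.474 0.6688 0.7349 0.7873 0.8179
#> Delta    0.474 0.4110 0.0989 0.0713 0.0388

logcpm <- voom_transform(filter_low_expression(cohort$expression))
degs   <- deg_intersection(pairwise_moderated_t(logcpm, cc$final_labels))
tme    <- build_tme_score(logcpm, degs, cc$final_labels, cohort$clinical,
                          n_resamples = 100, seed = 9)
tme
#> TMEScoreResult: 120 samples, cutpoint 2.704 (maxstat 5.17, p 0.000999), high/low = 77/43

idx <- match(names(tme$tme_score), cohort$clinical$sample_id)
cox_fit(cohort$clinical$os_time[idx], cohort$clinical$os_event[idx],
        data.frame(low = as.integer(tme$group == "low")))
#> CoxFit:
#>       HR      95% CI        p
#> low 3.39 2.079-5.526 9.83e-07
```

Three infiltration patterns are recovered (chosen K = 3: its relative
CDF-area gain of 0.41 is the last above the 0.1 elbow threshold), and
samples in the low-TME-score group have about 3.4-fold higher hazard than
the high-score group — the planted favourable pattern carries hazard ratio
0.5, so a high score marks better prognosis, matching the direction the
score is constructed to capture.

`run_pipeline(pipeline_config(seed = 1))` chains every stage (simulation
through mutational signatures and copy-number peaks) and writes per-stage
TSVs plus a JSON run manifest with derived stage seeds, file hashes and
wall times; `inst/scripts/tmepipe.R` is a thin command-line wrapper.

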