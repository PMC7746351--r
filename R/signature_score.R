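# TME gene-signature construction: random-forest reduction of cluster-
# associated genes, consensus gene clusters, PC1 signature scores, the TME
# score (favourable minus unfavourable cluster scores, directions from
# univariate Cox fits), and its prognostic cutpoint by the maximally
# selected standardized log-rank statistic.

#' Random-forest reduction of DEGs to signature genes
#'
#' Trains a random-forest classifier of cluster membership on gene
#' expression and keeps genes whose permutation importance (mean decrease
#' in accuracy) exceeds the mean importance.
#'
#' @param expr genes x samples matrix restricted to candidate genes.
#' @param labels cluster label per sample (>= 2 classes).
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return character vector of kept genes, with attributes `importance`
#'   (named numeric, all genes) and `oob_error`.
#' @export
rf_reduce <- function(expr, labels, n_trees = 1000, seed = 1L) {
  m <- as.matrix(expr)
  if (nrow(m) < 10) stop(">= 10 genes required")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop(">= 2 classes required")
  x <- t(m)
  fit <- with_seed(seed,
    randomForest(x = x, y = labels, ntree = n_trees, importance = TRUE))
  imp <- importance(fit, type = 1)[, 1]
  keep <- names(imp)[imp > mean(imp)]
  tme_log("rf_reduce: kept %d / %d genes (OOB error %.3f)",
          length(keep), nrow(m), mean(fit$err.rate[n_trees, "OOB"]))
  structure(keep, importance = imp,
            oob_error = unname(fit$err.rate[n_trees, "OOB"]))
}

#' Consensus clustering of signature genes
#'
#' Reuses [consensus_cluster()] on the z-scored gene x sample matrix (genes
#' as items) to define gene clusters.
#'
#' @param expr genes x samples matrix of the signature genes.
#' @param k_range candidate cluster numbers (default 2:5).
#' @param ... further arguments passed to [consensus_cluster()].
#' @return the `ConsensusResult`; `final_labels` maps gene -> cluster.
#' @export
cluster_genes <- function(expr, k_range = 2:5, ...) {
  z <- t(scale(t(as.matrix(expr))))
  z <- z[apply(is.finite(z), 1, all), , drop = FALSE]
  consensus_cluster(z, k_range = k_range, ...)
}

#' Per-cluster PC1 signature scores
#'
#' Each gene is z-scored across samples; the first principal component of
#' each cluster's gene block is extracted and each sample's score is its
#' PC1 projection. The PC1 sign is fixed so that the sum of gene loadings
#' is non-negative, preventing arbitrary sign flips between runs.
#'
#' @param expr genes x samples matrix (log scale).
#' @param gene_clusters named vector mapping gene -> cluster id.
#' @return A list of class `GeneClusterSet`: `scores` (samples x clusters),
#'   `loadings` (named list), `var_explained` (PC1 variance fraction per
#'   cluster), `gene_clusters`.
#' @export
score_gene_clusters <- function(expr, gene_clusters) {
  m <- as.matrix(expr)
  gene_clusters <- gene_clusters[names(gene_clusters) %in% rownames(m)]
  if (!length(gene_clusters)) stop("no cluster genes found in expression matrix")
  cl_ids <- sort(unique(gene_clusters))
  scores <- matrix(NA_real_, ncol(m), length(cl_ids),
                   dimnames = list(colnames(m), paste0("GC", cl_ids)))
  loadings <- vector("list", length(cl_ids))
  names(loadings) <- colnames(scores)
  varex <- setNames(numeric(length(cl_ids)), colnames(scores))
  for (i in seq_along(cl_ids)) {
    genes <- names(gene_clusters)[gene_clusters == cl_ids[i]]
    z <- t(scale(t(m[genes, , drop = FALSE])))
    z <- z[apply(is.finite(z), 1, all), , drop = FALSE]
    if (!nrow(z)) stop("cluster ", cl_ids[i], " has only zero-variance genes")
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
    load <- pc$rotation[, 1]
    if (sum(load) < 0) load <- -load
    scores[, i] <- as.vector(t(z) %*% load)
    loadings[[i]] <- load
    varex[i] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  structure(list(scores = scores, loadings = loadings,
                 var_explained = varex, gene_clusters = gene_clusters),
            class = "GeneClusterSet")
}

#' Prognostic direction of each gene cluster
#'
#' Fits a univariate Cox model of overall survival on each cluster's
#' signature score: hazard ratio < 1 marks the cluster favourable,
#' otherwise unfavourable.
#'
#' @param scores samples x clusters score matrix (rownames = sample ids).
#' @param clinical `ClinicalTable` covering the scored samples.
#' @return named character vector (`"favourable"`/`"unfavourable"`) with
#'   attribute `hr` (named numeric hazard ratios).
#' @export
cluster_directions <- function(scores, clinical) {
  idx <- match(rownames(scores), clinical$sample_id)
  if (anyNA(idx)) stop("clinical data missing for ",
                       sum(is.na(idx)), " scored sample(s)")
  hr <- vapply(seq_len(ncol(scores)), function(i) {
    fit <- coxph(Surv(clinical$os_time[idx], clinical$os_event[idx]) ~ scores[, i],
                 ties = "breslow")
    unname(exp(fit$coefficients))
  }, 0)
  names(hr) <- colnames(scores)
  dir <- ifelse(hr < 1, "favourable", "unfavourable")
  structure(dir, hr = hr)
}

#' Per-sample TME score
#'
#' TME score = sum of favourable-cluster signature scores minus sum of
#' unfavourable-cluster signature scores.
#'
#' @param scores samples x clusters score matrix.
#' @param directions named `"favourable"`/`"unfavourable"` vector, one per
#'   cluster (e.g. from [cluster_directions()]).
#' @return named numeric score per sample.
#' @export
compute_tme_score <- function(scores, directions) {
  if (!all(colnames(scores) %in% names(directions)))
    stop("every cluster needs a direction")
  directions <- directions[colnames(scores)]
  if (!all(directions %in% c("favourable", "unfavourable")))
    stop("directions must be 'favourable' or 'unfavourable'")
  sgn <- ifelse(directions == "favourable", 1, -1)
  setNames(as.vector(scores %*% sgn), rownames(scores))
}

# Standardized log-rank statistics for the binary splits score > cutpoint,
# vectorized over cutpoints. G: n x m logical matrix of group-1 membership.
logrank_z_splits <- function(time, event, G) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  Gm <- G[ord, , drop = FALSE]
  n <- length(t_s); m <- ncol(Gm)
  # at-risk counts: overall and per split (reverse cumulative sums)
  N1 <- apply(Gm, 2, function(g) rev(cumsum(rev(g))))
  Nall <- n - seq_len(n) + 1
  first <- !duplicated(t_s)                 # first row of each tied time
  grp <- cumsum(first)                      # tie-group index per row
  d <- as.numeric(tapply(e_s, grp, sum))    # events per unique time
  O1 <- rowsum(Gm * e_s, grp)               # group-1 events per unique time
  n_u <- Nall[first]
  n1_u <- N1[first, , drop = FALSE]
  keep <- d > 0
  d <- d[keep]; O1 <- O1[keep, , drop = FALSE]
  n_u <- n_u[keep]; n1_u <- n1_u[keep, , drop = FALSE]
  p1 <- n1_u / n_u
  E1 <- p1 * d
  Vu <- d * p1 * (1 - p1) *
    ifelse(n_u > 1, (n_u - d) / (n_u - 1), 0)
  U <- colSums(O1 - E1)
  V <- colSums(Vu)
  z <- ifelse(V > 0, U / sqrt(V), 0)
  as.vector(z)
}

#' Maximally selected log-rank cutpoint
#'
#' Candidate cutpoints are the observed score values within the quantile
#' range; for each, the standardized two-group log-rank statistic of the
#' split `score > cutpoint` is computed, and the cutpoint maximizing the
#' absolute statistic is chosen (ties toward the smaller cutpoint). The
#' p-value permutes the scores against the (time, event) pairs and compares
#' maximal statistics.
#'
#' @param score per-sample continuous score.
#' @param os_time,os_event survival outcome.
#' @param quantile_range candidate range as score quantiles.
#' @param n_perm permutations for the p-value (0 skips it).
#' @param seed integer seed.
#' @return list with `cutpoint`, `statistic` (max |standardized log-rank|),
#'   `p`, `candidates`, `z` (statistic per candidate).
#' @export
maxstat_cutpoint <- function(score, os_time, os_event,
                             quantile_range = c(0.1, 0.9),
                             n_perm = 1000, seed = 1L) {
  stopifnot(length(score) == length(os_time),
            length(score) == length(os_event))
  if (length(score) < 20) stop(">= 20 samples required")
  if (sum(os_event) < 5) stop(">= 5 events required")
  qs <- quantile(score, quantile_range)
  cand <- sort(unique(score[score >= qs[1] & score <= qs[2]]))
  cand <- cand[cand < max(score)]           # both groups non-empty
  if (!length(cand)) stop("no candidate cutpoints in the quantile range")
  G <- outer(score, cand, ">")
  z <- logrank_z_splits(os_time, os_event, G)
  best <- which.max(abs(z))                 # which.max takes the first = smaller cutpoint
  obs <- abs(z[best])
  p <- NA_real_
  if (n_perm > 0) {
    perm_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sp <- sample(score)
      max(abs(logrank_z_splits(os_time, os_event, outer(sp, cand, ">"))))
    }, 0))
    p <- (1 + sum(perm_max >= obs)) / (1 + n_perm)
  }
  list(cutpoint = cand[best], statistic = obs, p = p,
       candidates = cand, z = z)
}

#' End-to-end TME score from signature genes
#'
#' Convenience wrapper chaining random-forest reduction, gene-cluster
#' consensus clustering, PC1 scoring, Cox-based direction assignment, TME
#' score computation and maxstat dichotomization.
#'
#' @param expr genes x samples log-scale matrix.
#' @param degs candidate (common DEG) gene ids.
#' @param sample_clusters TME cluster label per sample (for the
#'   random-forest reduction).
#' @param clinical `ClinicalTable`.
#' @param n_trees random-forest trees.
#' @param gene_k_range candidate gene-cluster numbers.
#' @param n_resamples consensus resamples for gene clustering.
#' @param n_perm maxstat permutations.
#' @param seed integer seed.
#' @return A list of class `TMEScoreResult`: `tme_score`, `cutpoint`,
#'   `group` (`"high"`/`"low"`, high iff score > cutpoint), `statistic`,
#'   `p`, `signature_genes`, `gene_clusters`, `cluster_scores`,
#'   `directions`.
#' @export
build_tme_score <- function(expr, degs, sample_clusters, clinical,
                            n_trees = 1000, gene_k_range = 2:5,
                            n_resamples = 200, n_perm = 1000, seed = 1L) {
  m <- as.matrix(expr)
  degs <- intersect(degs, rownames(m))
  sig <- rf_reduce(m[degs, , drop = FALSE], sample_clusters,
                   n_trees = n_trees, seed = seed)
  gc <- cluster_genes(m[sig, , drop = FALSE], k_range = gene_k_range,
                      n_resamples = n_resamples, seed = seed + 1L)
  gcs <- score_gene_clusters(m, gc$final_labels)
  dir <- cluster_directions(gcs$scores, clinical)
  score <- compute_tme_score(gcs$scores, dir)
  idx <- match(names(score), clinical$sample_id)
  ms <- maxstat_cutpoint(score, clinical$os_time[idx], clinical$os_event[idx],
                         n_perm = n_perm, seed = seed + 2L)
  structure(list(tme_score = score, cutpoint = ms$cutpoint,
                 group = ifelse(score > ms$cutpoint, "high", "low"),
                 statistic = ms$statistic, p = ms$p,
                 signature_genes = as.character(sig),
                 gene_clusters = gc$final_labels,
                 cluster_scores = gcs$scores, directions = dir),
            class = "TMEScoreResult")
}

#' @export
print.TMEScoreResult <- function(x, ...) {
  cat(sprintf("TMEScoreResult: %d samples, cutpoint %.3f (maxstat %.2f, p %s), high/low = %d/%d\n",
              length(x$tme_score), x$cutpoint, x$statistic,
              format.pval(x$p), sum(x$group == "high"), sum(x$group == "low")))
  invisible(x)
}
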