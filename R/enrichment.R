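# Gene-set analyses: over-representation by the hypergeometric tail with BH
# correction, and GSEA with the weighted Kolmogorov-Smirnov running-sum
# enrichment score and gene-label permutation.

#' Over-representation analysis
#'
#' One-sided hypergeometric tail probability of observing at least the
#' overlap between the query and each set, within the stated universe;
#' BH-adjusted across sets. Set members outside the universe are ignored.
#'
#' @param query character vector of gene ids.
#' @param sets a `GeneSetCollection`.
#' @param universe background gene ids (must contain the query).
#' @return data.frame with `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `fdr`, ordered by p.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(normalize_gene_ids(universe))
  query <- unique(normalize_gene_ids(query))
  if (!all(query %in% universe))
    stop(sum(!(query %in% universe)), " query gene(s) outside the universe")
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- phyper(k - 1, length(s), N - length(s), nq, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = nq, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}

# Weighted KS running-sum enrichment score of one set on a ranked list.
# ranked: named metric values, decreasing order. Returns the signed maximal
# deviation of the running sum.
gsea_es <- function(ranked, set, p = 1) {
  hit <- names(ranked) %in% set
  nh <- sum(hit)
  if (nh == 0 || nh == length(ranked)) return(NA_real_)
  w <- abs(ranked)^p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (length(ranked) - nh))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Gene set enrichment analysis
#'
#' Subramanian-style weighted running-sum enrichment score on a ranked gene
#' list (weight `p = 1`), with significance by gene-label permutation:
#' random sets of the same size drawn from the ranked list. NES divides the
#' observed ES by the mean of same-sign permuted ES.
#'
#' @param ranked named numeric vector of the ranking metric (e.g.
#'   signal-to-noise or moderated t between two groups); sorted internally
#'   in decreasing order.
#' @param sets a `GeneSetCollection`.
#' @param n_perm permutations per set.
#' @param p weighting exponent.
#' @param min_size,max_size set-size bounds (after restriction to ranked
#'   genes).
#' @param seed integer seed.
#' @return data.frame with `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   ordered by p.
#' @export
gsea <- function(ranked, sets, n_perm = 1000, p = 1,
                 min_size = 3, max_size = 500, seed = 1L) {
  if (is.null(names(ranked))) stop("`ranked` must be named by gene id")
  names(ranked) <- normalize_gene_ids(names(ranked))
  ranked <- sort(ranked, decreasing = TRUE)
  rows <- with_seed(seed, lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], names(ranked))
    if (length(s) < min_size || length(s) > max_size) return(NULL)
    es <- gsea_es(ranked, s, p)
    perm <- vapply(seq_len(n_perm), function(i)
      gsea_es(ranked, sample(names(ranked), length(s)), p), 0)
    same <- perm[sign(perm) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    pval <- if (length(same)) (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
            else 1 / (1 + n_perm)
    data.frame(set = nm, size = length(s), es = es, nes = nes, p = pval,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set = character(), size = integer(),
                                      es = numeric(), nes = numeric(),
                                      p = numeric(), fdr = numeric()))
  out$fdr <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}

#' Signal-to-noise ranking metric between two groups
#'
#' (mean1 - mean2) / (sd1 + sd2), the classical GSEA default; standard
#' deviations are floored at 20% of the absolute mean (or 0.2) as in the
#' reference implementation.
#'
#' @param expr genes x samples matrix.
#' @param groups two-level label per sample; group 1 minus group 2 in level
#'   order.
#' @return named numeric vector.
#' @export
signal_to_noise <- function(expr, groups) {
  m <- as.matrix(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  i1 <- groups == levels(groups)[1]; i2 <- groups == levels(groups)[2]
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  s1 <- apply(m[, i1, drop = FALSE], 1, sd); s2 <- apply(m[, i2, drop = FALSE], 1, sd)
  floor_sd <- function(s, mu) pmax(s, pmax(0.2 * abs(mu), 0.2))
  setNames((m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2)), rownames(m))
}
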