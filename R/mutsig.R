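# Mutational signatures: 96-context catalogue construction with pyrimidine
# strand collapsing, signature extraction by automatic-relevance-
# determination NMF (KL divergence, half-normal priors, inverse-gamma
# hyperprior on per-signature relevance weights), cosine matching against a
# signature reference, exposure clustering, APOBEC TCW enrichment and
# tumor mutation burden.

#' Build a 96-context mutation catalogue
#'
#' Counts SNVs per sample in the 96 trinucleotide categories (see
#' [context_categories()]). Records with a purine reference are
#' reverse-complemented to the pyrimidine strand; non-SNV records and SNVs
#' without a valid 3-mer context are skipped with a logged count.
#'
#' @param muts a `MutationTable` with a `context` column.
#' @return A samples x 96 integer matrix of class `MutCatalogue`.
#' @export
build_catalogue <- function(muts) {
  stopifnot(inherits(muts, "MutationTable"))
  if (!"context" %in% colnames(muts)) stop("mutation table lacks a `context` column")
  snv <- is_snv(muts) & !is.na(muts$context) & nchar(muts$context) == 3
  skipped <- sum(!snv)
  if (skipped) tme_log("build_catalogue: skipped %d non-SNV/contextless record(s)", skipped)
  d <- muts[snv, , drop = FALSE]
  cat96 <- collapse_to_pyrimidine(d$ref, d$alt, d$context)
  ok <- !is.na(cat96)
  if (any(!ok)) tme_log("build_catalogue: %d record(s) with invalid context skipped", sum(!ok))
  cats <- context_categories()
  samples <- sort(unique(muts$sample_id))
  tab <- table(factor(d$sample_id[ok], levels = samples),
               factor(cat96[ok], levels = cats))
  m <- matrix(as.integer(tab), nrow(tab), 96, dimnames = list(samples, cats))
  structure(m, class = c("MutCatalogue", "matrix", "array"))
}

# Map (ref, alt, 3-mer context) to the pyrimidine-strand category label.
collapse_to_pyrimidine <- function(ref, alt, context) {
  pur <- ref %in% c("A", "G")
  ref2 <- ref; alt2 <- alt; ctx2 <- context
  if (any(pur)) {
    ref2[pur] <- chartr("ACGT", "TGCA", ref[pur])
    alt2[pur] <- chartr("ACGT", "TGCA", alt[pur])
    ctx2[pur] <- revcomp(context[pur])
  }
  out <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx2, 3, 3))
  out[!(out %in% context_categories())] <- NA
  out
}

# ---------------------------------------------------------------------------
# ARD NMF (KL divergence, half-normal priors)

# One run of multiplicative-update ARD NMF on V (96 x N). Per-signature
# relevance lambda_k carries an inverse-gamma(a, b) hyperprior; signatures
# whose mass collapses are pruned after convergence.
ard_nmf_once <- function(V, K0, a, b, tol, max_iter) {
  I <- nrow(V); J <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(runif(I * K0, 0, sqrt(mean(V))), I, K0)
  H <- matrix(runif(K0 * J, 0, sqrt(mean(V))), K0, J)
  lambda <- rep(b / (a + 1), K0)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) /
      (matrix(rowSums(H), I, K0, byrow = TRUE) + sweep(W, 2, lambda, "/") + eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) /
      (matrix(colSums(W), K0, J) + H / lambda + eps)
    lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b) /
      ((I + J) / 2 + a + 1)
    WH <- W %*% H + eps
    kl <- sum(V * log((V + eps) / WH) - V + WH)
    pen <- sum((0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b) / lambda) +
      ((I + J) / 2 + a + 1) * sum(log(lambda))
    obj <- kl + pen
    if (is.finite(obj_old) && abs(obj - obj_old) / max(abs(obj_old), eps) < tol) break
    obj_old <- obj
  }
  list(W = W, H = H, lambda = lambda, objective = obj, iterations = it)
}

#' Extract mutational signatures by ARD NMF
#'
#' Automatic-relevance-determination NMF with KL divergence and half-normal
#' priors: each of `K0` candidate signatures carries a relevance weight
#' under an inverse-gamma(`a`, `b`) hyperprior, and multiplicative updates
#' shrink irrelevant signatures to zero; the surviving count is the chosen
#' k. The best of `n_restarts` random restarts (lowest penalized objective)
#' is returned. `method = "plain"` instead runs unpenalized KL-NMF at each
#' fixed k in `k_range` and selects k by the reconstruction-error elbow.
#'
#' @param catalogue `MutCatalogue` (samples x 96) or compatible matrix.
#' @param k_range candidate k for `method = "plain"`; its maximum sets `K0`
#'   for the ARD method.
#' @param n_restarts random restarts (the reference setting is 1000; 100 is
#'   the desk-scale default).
#' @param tol relative convergence tolerance on the objective.
#' @param a inverse-gamma hyperparameter (default 10).
#' @param b inverse-gamma scale; default derived from the data as
#'   `sqrt((a-1)*(a-2)*mean(V)/K0)`.
#' @param max_iter update-iteration cap per restart.
#' @param method `"ard"` or `"plain"`.
#' @param prune_rel relative mass below which a signature is pruned.
#' @param reference signature reference for cosine matching (default the
#'   bundled synthetic COSMIC-v2-like matrix).
#' @param seed integer seed.
#' @return A list of class `SignatureDecomp`: `W` (96 x k, columns sum to
#'   1), `H` (k x samples, counts scale), `k`, `reconstruction_error`
#'   (Frobenius), `objective`, `match` (data.frame signature, best_match,
#'   cosine), `method`, `converged`.
#' @export
extract_signatures <- function(catalogue, k_range = 2:6, n_restarts = 100,
                               tol = 1e-7, a = 10, b = NULL, max_iter = 10000,
                               method = c("ard", "plain"), prune_rel = 1e-3,
                               reference = synthetic_cosmic_reference(),
                               seed = 1L) {
  method <- match.arg(method)
  V <- t(as.matrix(catalogue))               # 96 x samples
  if (ncol(V) < 2) stop(">= 2 samples required")
  if (sum(V) < 50) stop(">= 50 total mutations required")
  K0 <- max(k_range)
  if (is.null(b)) b <- sqrt((a - 1) * (a - 2) * mean(V) / K0)
  runs <- with_seed(seed, {
    if (method == "ard") {
      lapply(seq_len(n_restarts), function(i)
        ard_nmf_once(V, K0, a, b, tol, max_iter))
    } else {
      lapply(seq_len(n_restarts), function(i) {
        fits <- lapply(k_range, function(k) kl_nmf_once(V, k, tol, max_iter))
        fits[[plain_k_choice(fits, k_range)]]
      })
    }
  })
  best <- runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]
  mass <- colSums(best$W) * rowSums(best$H)
  keep <- mass > prune_rel * max(mass)
  W <- best$W[, keep, drop = FALSE]
  H <- best$H[keep, , drop = FALSE]
  # scale W columns to probability profiles, moving scale into H
  csum <- colSums(W)
  W <- sweep(W, 2, csum, "/")
  H <- H * csum
  k <- ncol(W)
  dimnames(W) <- list(rownames(V), paste0("SigDeNovo", seq_len(k)))
  dimnames(H) <- list(colnames(W), colnames(V))
  converged <- best$iterations < max_iter
  if (!converged)
    warning("NMF did not reach the convergence tolerance in the best restart; ",
            "best-effort result returned")
  match <- if (!is.null(reference)) cosine_match(W, reference) else NULL
  structure(list(W = W, H = H, k = k,
                 reconstruction_error = sqrt(sum((V - W %*% H)^2)),
                 objective = best$objective, match = match,
                 method = method, converged = converged),
            class = "SignatureDecomp")
}

# Plain KL-NMF at fixed k (no priors).
kl_nmf_once <- function(V, k, tol, max_iter) {
  I <- nrow(V); J <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(runif(I * k, 0, sqrt(mean(V))), I, k)
  H <- matrix(runif(k * J, 0, sqrt(mean(V))), k, J)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / (matrix(rowSums(H), I, k, byrow = TRUE) + eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (matrix(colSums(W), k, J) + eps)
    WH <- W %*% H + eps
    obj <- sum(V * log((V + eps) / WH) - V + WH)
    if (is.finite(obj_old) && abs(obj - obj_old) / max(abs(obj_old), eps) < tol) break
    obj_old <- obj
  }
  list(W = W, H = H, objective = obj, iterations = it)
}

# Elbow on KL error across k: largest k whose relative improvement over the
# previous k exceeds 5%.
plain_k_choice <- function(fits, k_range) {
  err <- vapply(fits, `[[`, 0, "objective")
  if (length(err) == 1) return(1L)
  rel <- -diff(err) / err[-length(err)]
  good <- which(rel > 0.05)
  if (!length(good)) 1L else max(good) + 1L
}

#' @export
print.SignatureDecomp <- function(x, ...) {
  cat(sprintf("SignatureDecomp: k = %d (%s NMF), reconstruction error %.1f\n",
              x$k, x$method, x$reconstruction_error))
  if (!is.null(x$match)) print(x$match)
  invisible(x)
}

#' Cosine similarity of two non-negative vectors
#' @param a,b numeric vectors of equal length.
#' @return scalar in [0, 1] for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Best cosine match of each signature against a reference
#'
#' @param W 96 x k signature matrix.
#' @param reference 96 x m reference signature matrix (rows aligned by
#'   category name when both are named).
#' @return data.frame with `signature`, `best_match`, `cosine`; ties go to
#'   the lowest reference column index.
#' @export
cosine_match <- function(W, reference) {
  R <- as.matrix(reference)
  if (!is.null(rownames(W)) && !is.null(rownames(R)) &&
      all(rownames(W) %in% rownames(R)))
    R <- R[rownames(W), , drop = FALSE]
  sims <- t(apply(W, 2, function(w)
    apply(R, 2, cosine_similarity, a = w)))
  best <- apply(sims, 1, which.max)           # which.max: first = lowest index
  data.frame(signature = colnames(W),
             best_match = colnames(R)[best],
             cosine = sims[cbind(seq_len(nrow(sims)), best)],
             stringsAsFactors = FALSE)
}

#' Cluster samples by signature exposures
#'
#' K-means on the column-normalized exposure matrix; the number of clusters
#' is chosen by mean silhouette width over `k_range`. Each cluster is
#' annotated with its top (highest mean-exposure) signature.
#'
#' @param H k x samples exposure matrix.
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @return list with `cluster` (named per sample), `k`, `silhouette`
#'   (named by k), `top_signature` (per cluster).
#' @export
cluster_exposures <- function(H, k_range = 2:6, seed = 1L) {
  X <- t(sweep(H, 2, pmax(colSums(H), 1e-12), "/"))   # samples x k, simplex rows
  k_range <- k_range[k_range < nrow(X)]
  if (!length(k_range)) stop("k_range exceeds the number of samples")
  with_seed(seed, {
    fits <- lapply(k_range, function(k)
      suppressWarnings(kmeans(X, k, nstart = 10, iter.max = 50)))
    sil <- vapply(fits, function(f) mean_silhouette(X, f$cluster), 0)
    names(sil) <- k_range
    best <- fits[[which.max(sil)]]
    top <- vapply(seq_len(max(best$cluster)), function(cl) {
      rownames(H)[which.max(rowMeans(H[, best$cluster == cl, drop = FALSE]))]
    }, "")
    list(cluster = setNames(best$cluster, rownames(X)),
         k = k_range[which.max(sil)], silhouette = sil,
         top_signature = top)
  })
}

# Mean silhouette width from Euclidean distances.
mean_silhouette <- function(X, cl) {
  d <- as.matrix(dist(X))
  n <- nrow(X)
  s <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    bs <- vapply(setdiff(unique(cl), cl[i]), function(k)
      mean(d[i, cl == k]), 0)
    if (!length(bs)) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# ---------------------------------------------------------------------------
# APOBEC enrichment

count_pattern <- function(strings, patterns) {
  rowSums(vapply(patterns, function(p) {
    vapply(gregexpr(p, strings, fixed = TRUE), function(g)
      if (g[1] == -1L) 0L else length(g), 0L)
  }, integer(length(strings))))
}

#' APOBEC TCW enrichment per sample
#'
#' For each sample, cytosine mutations (C>T, optionally plus C>G, after
#' pyrimidine collapsing) at TpCpW motifs (W = A/T) are compared with the
#' availability of TCW motifs among all cytosines in the +/-`flank` bp
#' windows around the mutated bases (both strands):
#' E = (mut_TCW / mut_C) / (context_TCW / context_C). Significance is a
#' one-sided Fisher test of the 2x2 table (mut_TCW, mut_C - mut_TCW;
#' context_TCW, context_C - context_TCW); samples with E > 2 are classed
#' `enriched`.
#'
#' @param muts `MutationTable` with `context` and `context41` columns.
#' @param flank half-window size actually carried by `context41` (20).
#' @param subs `"ctcg"` (default: C>T and C>G) or `"ct"`.
#' @return A data.frame of class `APOBECResult` with `sample_id`,
#'   `enrichment`, `fisher_p`, `class`, `mut_tcw`, `mut_c`, `context_tcw`,
#'   `context_c`.
#' @export
apobec_enrichment <- function(muts, flank = 20, subs = c("ctcg", "ct")) {
  subs <- match.arg(subs)
  stopifnot(inherits(muts, "MutationTable"))
  if (!all(c("context", "context41") %in% colnames(muts)))
    stop("mutation table needs `context` and `context41` columns (+/-20 bp windows)")
  snv <- is_snv(muts) & !is.na(muts$context41)
  d <- muts[snv, , drop = FALSE]
  cat96 <- collapse_to_pyrimidine(d$ref, d$alt, d$context)
  sub <- substr(cat96, 3, 5)
  wanted <- if (subs == "ctcg") c("C>T", "C>G") else "C>T"
  use <- !is.na(sub) & sub %in% wanted
  d <- d[use, , drop = FALSE]
  cat96 <- cat96[use]
  is_tcw <- substr(cat96, 1, 1) == "T" & substr(cat96, 7, 7) %in% c("A", "T")
  out <- do.call(rbind, lapply(sort(unique(muts$sample_id)), function(s) {
    i <- d$sample_id == s
    mut_c <- sum(i)
    mut_tcw <- sum(i & is_tcw)
    win <- d$context41[i]
    ctx_c <- sum(count_pattern(win, c("C", "G")))
    ctx_tcw <- sum(count_pattern(win, c("TCA", "TCT", "TGA", "AGA")))
    if (mut_c == 0 || ctx_c == 0 || ctx_tcw == 0) {
      e <- 0; p <- 1
    } else {
      e <- (mut_tcw / mut_c) / (ctx_tcw / ctx_c)
      p <- fisher.test(matrix(c(mut_tcw, mut_c - mut_tcw,
                                ctx_tcw, ctx_c - ctx_tcw), 2, byrow = TRUE),
                       alternative = "greater")$p.value
    }
    data.frame(sample_id = s, enrichment = e, fisher_p = p,
               class = if (e > 2) "enriched" else "non-enriched",
               mut_tcw = mut_tcw, mut_c = mut_c,
               context_tcw = ctx_tcw, context_c = ctx_c,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("APOBECResult", "data.frame")
  out
}

#' Genes over-represented among APOBEC-enriched samples
#'
#' Per gene, a one-sided Fisher test of the 2x2 table of samples mutated in
#' the gene versus APOBEC enrichment class, BH-corrected.
#'
#' @param muts `MutationTable` with a `gene` column.
#' @param apobec an `APOBECResult` covering the samples.
#' @return data.frame with `gene`, `mutated_enriched`, `mutated_other`,
#'   `p`, `fdr`, ordered by p.
#' @export
apobec_gene_association <- function(muts, apobec) {
  if (!"gene" %in% colnames(muts)) stop("mutation table lacks a `gene` column")
  enr <- setNames(apobec$class == "enriched", apobec$sample_id)
  samples <- names(enr)
  rows <- lapply(sort(unique(muts$gene)), function(g) {
    mut_samp <- unique(muts$sample_id[muts$gene == g])
    m_e <- sum(enr[mut_samp]); m_o <- length(mut_samp) - m_e
    u_e <- sum(enr) - m_e; u_o <- sum(!enr) - m_o
    p <- fisher.test(matrix(c(m_e, m_o, u_e, u_o), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(gene = g, mutated_enriched = m_e, mutated_other = m_o, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}

#' Tumor mutation burden per sample
#'
#' Counts non-silent mutations (the nine recognised classes) per sample,
#' raw and per exome megabase.
#'
#' @param muts `MutationTable`.
#' @param nonsilent_classes classes counted (default [VARIANT_CLASSES]).
#' @param exome_mb exome size in Mb for the normalized rate.
#' @return data.frame with `sample_id`, `n_nonsilent`, `tmb_per_mb`.
#' @export
compute_tmb <- function(muts, nonsilent_classes = VARIANT_CLASSES, exome_mb = 38) {
  samples <- sort(unique(muts$sample_id))
  n <- vapply(samples, function(s)
    sum(muts$sample_id == s & muts$variant_class %in% nonsilent_classes), 0L)
  data.frame(sample_id = samples, n_nonsilent = n,
             tmb_per_mb = n / exome_mb,
             stringsAsFactors = FALSE, row.names = NULL)
}
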