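# Differential expression among TME clusters: low-expression filtering,
# log-CPM (voom-style) transformation, and an empirical-Bayes moderated
# two-sample t-test with method-of-moments estimation of the variance prior
# (Smyth-style), plus the raw-p / fold-change significance rule and the
# across-contrast "common DEG" intersection.

#' Filter genes with low counts
#'
#' Keeps genes with at least `min_count` in at least `min_samples_frac` of
#' samples (both boundaries inclusive); gene order is preserved.
#'
#' @param counts `ExpressionMatrix` with unit `counts`.
#' @param min_count count threshold.
#' @param min_samples_frac required fraction of samples at or above it.
#' @return filtered `ExpressionMatrix`.
#' @export
filter_low_expression <- function(counts, min_count = 10, min_samples_frac = 0.2) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (expression_unit(counts) != "counts") stop("unit must be 'counts'")
  m <- as.matrix(counts)
  keep <- rowMeans(m >= min_count) >= min_samples_frac
  tme_log("filter_low_expression: keeping %d / %d genes", sum(keep), nrow(m))
  expression_matrix(m[keep, , drop = FALSE], unit = "counts")
}

#' Log-CPM (voom-style) transformation
#'
#' logcpm = log2((count + 0.5) / (libsize + 1) * 1e6). Optional precision
#' weights follow the voom recipe: a lowess trend of the square-root
#' residual standard deviation against mean log2 count, interpolated per
#' observation and returned as inverse fourth-power weights.
#'
#' @param counts `ExpressionMatrix` with unit `counts`.
#' @param weights also compute precision weights (needs a `groups` factor
#'   for residuals; off by default).
#' @param groups optional group labels used for residual variances when
#'   `weights = TRUE`.
#' @return `ExpressionMatrix` with unit `logcpm`; when `weights = TRUE`, the
#'   weight matrix is attached as attribute `"weights"`.
#' @export
voom_transform <- function(counts, weights = FALSE, groups = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (expression_unit(counts) != "counts") stop("unit must be 'counts'")
  m <- as.matrix(counts)
  lib <- colSums(m)
  logcpm <- log2(sweep(m + 0.5, 2, lib + 1, "/") * 1e6)
  out <- expression_matrix(logcpm, unit = "logcpm")
  if (weights) {
    if (is.null(groups)) groups <- rep(1, ncol(m))
    groups <- as.factor(groups)
    fitted <- t(apply(logcpm, 1, function(y) ave(y, groups)))
    res_sd <- sqrt(rowSums((logcpm - fitted)^2) /
                     pmax(ncol(m) - nlevels(groups), 1))
    mean_logcount <- rowMeans(log2(m + 0.5))
    lo <- lowess(mean_logcount, sqrt(res_sd), f = 0.5)
    # observation-level predicted sqrt-SD from the trend, on fitted log-cpm
    obs_logcount <- logcpm + log2(lib + 1) - log2(1e6) # back to log2 count scale
    pred <- approx(lo$x, lo$y, xout = as.vector(obs_logcount), rule = 2)$y
    w <- matrix(pred, nrow(m), ncol(m))^-4
    dimnames(w) <- dimnames(m)
    attr(out, "weights") <- w
  }
  out
}

# Numerical inverse of trigamma by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, 0)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior:
# log s^2 has mean log s0^2 + digamma terms and variance trigamma(d/2) +
# trigamma(d0/2); solve for (d0, s0^2).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- mean(e)
  vv <- var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (!is.finite(vv) || vv <= 0) {
    d0 <- Inf
    s0 <- exp(ev)
  } else {
    d0 <- 2 * trigamma_inverse(vv)
    s0 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0)
}

#' Moderated two-group t-test
#'
#' Per gene: log2FC is the mean difference between groups; the pooled
#' residual variance is shrunk toward a prior variance `s0^2` with prior
#' degrees of freedom `d0`, both estimated by method of moments on the
#' log residual variances; the moderated t has `d0 + d_g` degrees of
#' freedom. The significance flag applies `p < p_thresh` and
#' `|log2FC| > lfc_thresh`.
#'
#' @param expr `ExpressionMatrix` (log scale) or numeric matrix, genes x
#'   samples.
#' @param groups vector of two group labels, one per sample; log2FC is
#'   group1 minus group2 in `sort(unique(groups))` order unless `groups` is
#'   a factor, whose level order is respected.
#' @param p_thresh,lfc_thresh significance rule thresholds.
#' @param prior_df optional forced prior df: `0` reduces to the ordinary
#'   pooled t-test, `Inf` to a z-like test with the global prior variance.
#' @return A `data.frame` of class `DGEResult` with columns `gene`,
#'   `log2fc`, `mean_expr`, `t`, `df`, `p`, `fdr`, `significant`, and
#'   attributes `d0`, `s0_sq`.
#' @export
moderated_t <- function(expr, groups, p_thresh = 1e-3, lfc_thresh = 1,
                        prior_df = NULL) {
  m <- as.matrix(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  if (length(i1) < 2 || length(i2) < 2) stop(">= 2 samples per group required")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, var)
  v2 <- apply(m[, i2, drop = FALSE], 1, var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, dg)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_sq = 0)
  } else if (is.infinite(prior_df)) {
    prior <- list(d0 = Inf, s0_sq = exp(mean(log(s2[s2 > 0]))))
  } else {
    prior <- list(d0 = prior_df, s0_sq = fit_variance_prior(s2, dg)$s0_sq)
  }
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    post_var <- rep(s0, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    post_var <- (d0 * s0 + dg * s2) / (d0 + dg)
    df_total <- rep(d0 + dg, length(s2))
  }
  # zero-variance floor: a gene constant in both groups gets the prior
  # variance (p = 1 when the fold change is also 0)
  zero_var <- post_var <= 0
  if (any(zero_var)) {
    floor_var <- if (s0 > 0) s0 else min(post_var[!zero_var], na.rm = TRUE)
    if (!is.finite(floor_var) || floor_var <= 0) floor_var <- 1e-12
    post_var[zero_var] <- floor_var
    tme_log("moderated_t: %d zero-variance gene(s) floored to prior variance",
            sum(zero_var))
  }
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  tstat <- lfc / se
  p <- ifelse(is.infinite(df_total),
              2 * pnorm(-abs(tstat)),
              2 * pt(-abs(tstat), df_total))
  p[zero_var & lfc == 0] <- 1
  res <- data.frame(gene = rownames(m), log2fc = lfc,
                    mean_expr = (m1 * n1 + m2 * n2) / (n1 + n2),
                    t = tstat, df = df_total, p = p,
                    fdr = p.adjust(p, "BH"),
                    significant = p < p_thresh & abs(lfc) > lfc_thresh,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0
  class(res) <- c("DGEResult", "data.frame")
  res
}

#' Pairwise moderated-t contrasts across clusters
#'
#' Runs [moderated_t()] for every pair of cluster labels (one-vs-one).
#'
#' @param expr log-scale matrix, genes x samples.
#' @param labels cluster label per sample.
#' @param ... passed to [moderated_t()].
#' @return named list of `DGEResult`, names like `"1v2"`.
#' @export
pairwise_moderated_t <- function(expr, labels, ...) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  pairs <- utils::combn(lev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- labels %in% pairs[, i]
    moderated_t(as.matrix(expr)[, keep, drop = FALSE],
                factor(labels[keep], levels = pairs[, i]), ...)
  })
  names(out) <- apply(pairs, 2, paste, collapse = "v")
  out
}

#' Common DEGs across pairwise contrasts
#'
#' A gene is "common" when it is significant in at least `min_contrasts` of
#' the supplied contrasts (`rule = "two"`, the default); `"any"` and
#' `"all"` set the requirement to 1 or all contrasts.
#'
#' @param results list of `DGEResult` (one per contrast).
#' @param rule `"two"`, `"any"` or `"all"`.
#' @return character vector of common DEG ids.
#' @export
deg_intersection <- function(results, rule = c("two", "any", "all")) {
  rule <- match.arg(rule)
  sig <- lapply(results, function(r) r$gene[r$significant])
  need <- switch(rule, any = 1L, two = min(2L, length(results)),
                 all = length(results))
  tab <- table(unlist(sig))
  out <- names(tab)[tab >= need]
  tme_log("deg_intersection (rule=%s): %d common DEGs from contrasts of size %s",
          rule, length(out), paste(vapply(sig, length, 1L), collapse = "/"))
  out
}
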