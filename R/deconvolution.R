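# Immune-cell deconvolution by nu-support-vector regression against a
# cell-type signature matrix, following the CIBERSORT algorithm: jointly
# standardize the signature matrix on the intersected genes, standardize
# each mixture column by its own mean/SD on the same genes, fit linear-
# kernel nu-SVR at nu in {0.25, 0.5, 0.75}, keep the fit with the smallest
# RMSE, clip negative coefficients and renormalize to the simplex. The
# permutation p-value compares each sample's fit correlation against a
# shared null distribution built from gene-shuffled mixtures.

#' Estimate cell-type fractions from bulk expression
#'
#' @param mixture `ExpressionMatrix` on a linear (non-log) scale.
#' @param reference `SignatureMatrixRef` (default: the bundled synthetic
#'   22-type matrix from [synthetic_lm22()]).
#' @param n_permutations permutations for the null correlation distribution;
#'   0 skips p-values.
#' @param nu_grid candidate nu values for the SVR.
#' @param quantile_norm apply rank-based quantile normalization of the
#'   mixture columns to their mean distribution first (off by default, as
#'   recommended for RNA-seq).
#' @param seed integer seed for the permutation null.
#' @return A list of class `CellFractions`: `fractions` (samples x types,
#'   rows on the simplex), `rmse`, `pearson_r`, `permutation_p` (NA when
#'   `n_permutations = 0`), `nu`, `degenerate` (samples whose coefficients
#'   were all non-positive, reported as uniform fractions), and
#'   `n_permutations`.
#' @export
deconvolve <- function(mixture, reference = synthetic_lm22(),
                       n_permutations = 1000,
                       nu_grid = c(0.25, 0.5, 0.75),
                       quantile_norm = FALSE, seed = 1L) {
  M <- as.matrix(mixture)
  R <- as.matrix(reference)
  common <- intersect(rownames(R), rownames(M))
  overlap <- length(common) / nrow(R)
  if (overlap < 0.5)
    stop(sprintf("only %.0f%% of reference genes present in mixture (need >= 50%%)",
                 100 * overlap))
  if (max(M) < 50)
    warning("mixture maximum < 50; input looks log-scaled but a linear scale is required")
  if (quantile_norm) M <- quantile_normalize(M)
  X <- R[common, , drop = FALSE]
  Y <- M[common, , drop = FALSE]
  X <- (X - mean(X)) / sd(as.vector(X))   # joint standardization of the reference

  n_samp <- ncol(Y)
  n_types <- ncol(R)
  fractions <- matrix(0, n_samp, n_types, dimnames = list(colnames(Y), colnames(R)))
  rmse <- r <- nu_used <- setNames(numeric(n_samp), colnames(Y))
  degenerate <- setNames(logical(n_samp), colnames(Y))
  for (j in seq_len(n_samp)) {
    fit <- svr_fit_one(X, Y[, j], nu_grid)
    fractions[j, ] <- fit$w
    rmse[j] <- fit$rmse; r[j] <- fit$r; nu_used[j] <- fit$nu
    degenerate[j] <- fit$degenerate
  }
  perm_p <- rep(NA_real_, n_samp)
  if (n_permutations > 0) {
    null_r <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      yp <- sample(as.vector(Y), nrow(Y))
      svr_fit_one(X, yp, nu_grid)$r
    }, 0))
    perm_p <- vapply(r, function(ri) mean(null_r >= ri), 0)
  }
  structure(list(fractions = fractions, rmse = rmse, pearson_r = r,
                 permutation_p = setNames(perm_p, colnames(Y)),
                 nu = nu_used, degenerate = degenerate,
                 n_permutations = n_permutations),
            class = "CellFractions")
}

# One mixture column against the standardized reference: best-nu SVR fit.
svr_fit_one <- function(X, y, nu_grid) {
  ys <- (y - mean(y)) / sd(y)
  best <- NULL
  for (nu in nu_grid) {
    mod <- svm(X, ys, type = "nu-regression", kernel = "linear",
               nu = nu, scale = FALSE)
    w <- as.vector(t(mod$coefs) %*% mod$SV)
    wp <- pmax(w, 0)
    if (sum(wp) > 0) {
      wn <- wp / sum(wp)
      fitted <- as.vector(X %*% wn)
      rmse <- sqrt(mean((fitted - ys)^2))
      r <- suppressWarnings(cor(fitted, ys))
      if (!is.finite(r)) r <- 0
      deg <- FALSE
    } else {
      wn <- rep(1 / ncol(X), ncol(X))
      rmse <- Inf; r <- 0; deg <- TRUE
    }
    if (is.null(best) || rmse < best$rmse)
      best <- list(w = wn, rmse = rmse, r = r, nu = nu, degenerate = deg)
  }
  if (!is.finite(best$rmse)) best$rmse <- NA_real_
  best
}

quantile_normalize <- function(m) {
  rk <- apply(m, 2, rank, ties.method = "average")
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(rk, 2, function(r) approx(seq_len(nrow(m)), target, xout = r)$y)
  dimnames(out) <- dimnames(m)
  out
}

#' @export
print.CellFractions <- function(x, ...) {
  cat(sprintf("CellFractions: %d samples x %d cell types (mean RMSE %.3f, mean r %.3f)\n",
              nrow(x$fractions), ncol(x$fractions),
              mean(x$rmse, na.rm = TRUE), mean(x$pearson_r)))
  invisible(x)
}

#' Write cell fractions plus diagnostics as TSV
#' @param x a `CellFractions`.
#' @param path output path.
#' @export
write_fractions <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$fractions), x$fractions,
                   RMSE = x$rmse, Pearson_r = x$pearson_r,
                   P_value = x$permutation_p, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
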