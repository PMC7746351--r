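# Monti-style resampling consensus clustering with CDF-area selection of K.

#' Consensus clustering over a range of K
#'
#' For each K, items are subsampled `n_resamples` times, the base clustering
#' is run on each subsample, and the consensus for a pair of items is the
#' number of times they co-clustered divided by the number of times they
#' were co-sampled. Final labels per K come from average-linkage
#' hierarchical clustering of 1 - consensus. The number of clusters is
#' chosen from the consensus CDF areas by [select_k()].
#'
#' @param features items x dims numeric matrix.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param n_resamples number of subsampling iterations.
#' @param subsample fraction of items drawn per iteration.
#' @param base base clustering: `"kmeans"` (Lloyd with `nstart` restarts) or
#'   `"hclust"` (Euclidean/Ward).
#' @param nstart k-means restarts per iteration.
#' @param seed integer seed.
#' @return A list of class `ConsensusResult`: `consensus` (list of item x
#'   item matrices per K), `labels` (list per K), `cdf_area` (named numeric),
#'   `delta_area`, `chosen_k`, `final_labels` (labels at `chosen_k`),
#'   `n_resamples`, `seed`.
#' @export
consensus_cluster <- function(features, k_range = 2:6, n_resamples = 1000,
                              subsample = 0.8, base = c("kmeans", "hclust"),
                              nstart = 10, seed = 1L) {
  base <- match.arg(base)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 10) stop("need >= 10 items")
  if (ncol(features) < 1 || any(!is.finite(features)))
    stop("features must be a finite matrix with >= 1 column")
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  k_range <- sort(unique(as.integer(k_range)))
  drop_k <- k_range >= n
  if (any(drop_k)) {
    warning("skipping K >= number of items: ",
            paste(k_range[drop_k], collapse = ", "))
    k_range <- k_range[!drop_k]
  }
  if (!length(k_range)) stop("no usable K in k_range")
  m <- max(2L, floor(subsample * n))
  consensus <- labels <- vector("list", length(k_range))
  names(consensus) <- names(labels) <- as.character(k_range)
  with_seed(seed, {
    # co-sampling counts do not depend on K only on the drawn subsamples;
    # draw one subsample sequence per K so runs are independent across K.
    for (ki in seq_along(k_range)) {
      K <- k_range[ki]
      co_cluster <- matrix(0, n, n)
      co_sample <- matrix(0, n, n)
      for (b in seq_len(n_resamples)) {
        idx <- sample.int(n, m)
        cl <- base_cluster(features[idx, , drop = FALSE], K, base, nstart)
        co_sample[idx, idx] <- co_sample[idx, idx] + 1
        for (g in split(idx, cl))
          co_cluster[g, g] <- co_cluster[g, g] + 1
      }
      cons <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
      if (any(co_sample == 0 & upper.tri(co_sample)))
        warning("item pair(s) never co-sampled at K = ", K,
                "; consensus entry set to 0")
      diag(cons) <- 1
      dimnames(cons) <- list(ids, ids)
      consensus[[ki]] <- cons
      hc <- hclust(as.dist(1 - cons), method = "average")
      labels[[ki]] <- setNames(cutree(hc, K), ids)
    }
  })
  areas <- vapply(consensus, function(cm) cdf_area(cm[upper.tri(cm)]), 0)
  names(areas) <- as.character(k_range)
  sel <- select_k(areas)
  structure(list(consensus = consensus, labels = labels,
                 cdf_area = areas, delta_area = sel$delta,
                 chosen_k = sel$chosen_k,
                 final_labels = labels[[as.character(sel$chosen_k)]],
                 k_range = k_range, n_resamples = n_resamples, seed = seed),
            class = "ConsensusResult")
}

base_cluster <- function(x, K, base, nstart) {
  if (base == "kmeans") {
    km <- suppressWarnings(kmeans(x, centers = kmeanspp_centers(x, K),
                                  algorithm = "Lloyd", iter.max = 50))
    if (nstart > 1) {
      for (i in seq_len(nstart - 1)) {
        cand <- suppressWarnings(kmeans(x, centers = kmeanspp_centers(x, K),
                                        algorithm = "Lloyd", iter.max = 50))
        if (cand$tot.withinss < km$tot.withinss) km <- cand
      }
    }
    km$cluster
  } else {
    cutree(hclust(dist(x), method = "ward.D2"), K)
  }
}

# k-means++ seeding: spread initial centers by squared-distance sampling,
# maintaining the running minimum squared distance to the chosen centers.
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  pick <- integer(K)
  pick[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[pick[1], ], "-")^2)
  if (K > 1) for (k in 2:K) {
    pick[k] <- if (all(d2 == 0)) sample.int(n, 1)
               else sample.int(n, 1, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[pick[k], ], "-")^2))
  }
  centers <- x[pick, , drop = FALSE]
  centers + matrix(rnorm(length(centers), 0, 1e-9), nrow(centers)) # break exact ties
}

#' Area under the consensus CDF
#'
#' The empirical CDF of the consensus values is integrated over [0, 1]
#' (right-continuous step function).
#'
#' @param values consensus values (upper triangle of a consensus matrix).
#' @return scalar area.
#' @export
cdf_area <- function(values) {
  xs <- sort(unique(c(0, values, 1)))
  F <- ecdf(values)
  sum(diff(xs) * F(xs[-length(xs)]))
}

#' Choose K from consensus CDF areas
#'
#' The relative area increase is Delta(K) = (A(K) - A(K-1)) / A(K-1) for
#' consecutive K, with Delta at the smallest K defined as A itself. The
#' chosen K is the largest K whose Delta exceeds `threshold`; if none does,
#' the smallest K is returned (no elbow).
#'
#' @param areas named numeric vector of CDF areas, names = K.
#' @param threshold relative-increase threshold (default 0.1).
#' @return list with `chosen_k` and `delta` (named numeric).
#' @export
select_k <- function(areas, threshold = 0.1) {
  ks <- as.integer(names(areas))
  if (is.null(names(areas)) || any(is.na(ks)))
    stop("`areas` must be named by K")
  ord <- order(ks)
  ks <- ks[ord]; areas <- areas[ord]
  if (length(ks) == 1) {
    warning("single K supplied; returning it")
    return(list(chosen_k = ks, delta = setNames(areas, ks)))
  }
  delta <- c(areas[1], diff(areas) / areas[-length(areas)])
  names(delta) <- ks
  above <- ks[delta > threshold]
  chosen <- if (length(above)) max(above) else min(ks)
  list(chosen_k = chosen, delta = delta)
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: K in {%s}, chosen K = %d (%d resamples)\n",
              paste(x$k_range, collapse = ","), x$chosen_k, x$n_resamples))
  print(round(rbind(`CDF area` = x$cdf_area, `Delta` = x$delta_area), 4))
  invisible(x)
}
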