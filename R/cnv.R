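# GISTIC-like copy-number scoring: arm-level gain/loss frequencies and
# per-bin amplification/deletion G-scores with an empirical null from
# cyclic permutation of each sample's genome-wide bin profile, BH q-values
# and peak calling.

#' Arm-level gain/loss frequencies
#'
#' A sample carries an arm gain when segments with value above
#' `amp_thresh` cover at least `arm_frac` of the arm's length (symmetric
#' for losses below `del_thresh`).
#'
#' @param segs `SegmentTable`.
#' @param arms arm definition data.frame (`chrom`, `arm`, `start`, `end`);
#'   default the bundled toy genome.
#' @param amp_thresh,del_thresh segment-value thresholds.
#' @param arm_frac required covered fraction of the arm.
#' @return data.frame with `arm`, `gain_freq`, `loss_freq`, `n_samples`.
#' @export
arm_level <- function(segs, arms = toy_genome_arms(),
                      amp_thresh = 1, del_thresh = -1, arm_frac = 0.5) {
  stopifnot(inherits(segs, "SegmentTable"))
  samples <- sort(unique(segs$sample_id))
  res <- lapply(seq_len(nrow(arms)), function(ai) {
    a <- arms[ai, ]
    arm_len <- a$end - a$start + 1
    on_arm <- segs$chrom == a$chrom & segs$end >= a$start & segs$start <= a$end
    d <- segs[on_arm, , drop = FALSE]
    ov <- pmin(d$end, a$end) - pmax(d$start, a$start) + 1
    gain <- tapply(ov * (d$value > amp_thresh), factor(d$sample_id, samples), sum)
    loss <- tapply(ov * (d$value < del_thresh), factor(d$sample_id, samples), sum)
    gain[is.na(gain)] <- 0; loss[is.na(loss)] <- 0
    data.frame(arm = a$arm,
               gain_freq = mean(gain >= arm_frac * arm_len),
               loss_freq = mean(loss >= arm_frac * arm_len),
               n_samples = length(samples),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Fixed-width genome bins from an arm table.
make_bins <- function(arms, bin_size) {
  chroms <- unique(arms$chrom)
  out <- lapply(chroms, function(ch) {
    len <- max(arms$end[arms$chrom == ch])
    start <- seq(1, len, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size - 1, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-sample per-bin qualifying amplitude: the maximal |value| among
# overlapping segments beyond the threshold (0 when none qualifies). Using
# the maximum makes scores invariant to segment fragmentation.
bin_amplitude <- function(segs, bins, thresh, direction) {
  n_bins <- nrow(bins)
  samples <- sort(unique(segs$sample_id))
  amp <- matrix(0, length(samples), n_bins,
                dimnames = list(samples, NULL))
  qual <- if (direction == "amp") segs$value > thresh else segs$value < thresh
  d <- segs[qual, , drop = FALSE]
  if (!nrow(d)) return(amp)
  for (ch in unique(d$chrom)) {
    bi <- which(bins$chrom == ch)
    di <- which(d$chrom == ch)
    for (r in di) {
      hit <- bi[bins$start[bi] <= d$end[r] & bins$end[bi] >= d$start[r]]
      if (!length(hit)) next
      s <- d$sample_id[r]
      amp[s, hit] <- pmax(amp[s, hit], abs(d$value[r]))
    }
  }
  amp
}

#' G-score profile with permutation q-values and peak calling
#'
#' Per bin and direction, the G-score is the sum over samples of the
#' qualifying aberration amplitude (value beyond `amp_thresh` /
#' `del_thresh`), combining frequency and amplitude. The null distribution
#' cyclically shifts each sample's genome-wide bin profile by a random
#' offset `n_perm` times; empirical p-values (pooled over bins and
#' permutations within a direction) are BH-corrected, and peaks are maximal
#' runs of adjacent same-chromosome bins with q below `q_thresh`, reported
#' with their maximal-G bin.
#'
#' @param segs `SegmentTable`.
#' @param arms arm/chromosome definitions (default toy genome).
#' @param bin_size bin width in bp (default 1 Mb).
#' @param amp_thresh,del_thresh qualifying thresholds; explicit values
#'   override the preset.
#' @param preset `"integer"` (+/-1, suited to integer-like copy-number
#'   values) or `"log2"` (+/-0.1, the conventional log2-ratio scale).
#' @param n_perm cyclic permutations.
#' @param q_thresh peak-calling q threshold.
#' @param seed integer seed.
#' @return A list of class `GScoreProfile`: `bins` (data.frame chrom,
#'   start, end, g_amp, g_del, q_amp, q_del, covered), `arm_table`, `peaks`
#'   (data.frame chrom, start, end, direction, q, peak_bin_start), and the
#'   parameters used.
#' @export
gscore <- function(segs, arms = toy_genome_arms(), bin_size = 1e6,
                   amp_thresh = NULL, del_thresh = NULL,
                   preset = c("integer", "log2"),
                   n_perm = 1000, q_thresh = 0.25, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(amp_thresh)) amp_thresh <- if (preset == "integer") 1 else 0.1
  if (is.null(del_thresh)) del_thresh <- if (preset == "integer") -1 else -0.1
  stopifnot(inherits(segs, "SegmentTable"))
  bins <- make_bins(arms, bin_size)
  covered <- bin_coverage(segs, bins)
  amp <- bin_amplitude(segs, bins, amp_thresh, "amp")
  del <- bin_amplitude(segs, bins, del_thresh, "del")
  g_amp <- colSums(amp)
  g_del <- colSums(del)
  q_amp <- perm_q(amp, g_amp, n_perm, seed)
  q_del <- perm_q(del, g_del, n_perm, seed + 1L)
  q_amp[!covered] <- 1
  q_del[!covered] <- 1
  bins$g_amp <- g_amp; bins$g_del <- g_del
  bins$q_amp <- q_amp; bins$q_del <- q_del
  bins$covered <- covered
  peaks <- rbind(call_peaks(bins, "amp", q_thresh),
                 call_peaks(bins, "del", q_thresh))
  structure(list(bins = bins, arm_table = arm_level(segs, arms,
                                                    amp_thresh = amp_thresh,
                                                    del_thresh = del_thresh),
                 peaks = peaks, amp_thresh = amp_thresh,
                 del_thresh = del_thresh, n_perm = n_perm,
                 q_thresh = q_thresh, bin_size = bin_size, seed = seed),
            class = "GScoreProfile")
}

bin_coverage <- function(segs, bins) {
  covered <- logical(nrow(bins))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    di <- which(segs$chrom == ch)
    if (!length(di)) next
    for (b in bi)
      covered[b] <- any(segs$start[di] <= bins$end[b] &
                          segs$end[di] >= bins$start[b])
  }
  covered
}

# Empirical p by pooled cyclic-shift null, then BH. amp: samples x bins.
perm_q <- function(amp, g_obs, n_perm, seed) {
  n_bins <- ncol(amp); n_samp <- nrow(amp)
  if (n_perm <= 0 || all(g_obs == 0))
    return(rep(1, n_bins))
  exceed <- numeric(length(g_obs))
  total <- 0
  with_seed(seed, for (p in seq_len(n_perm)) {
    g_null <- numeric(n_bins)
    offs <- sample.int(n_bins, n_samp, replace = TRUE)
    for (s in seq_len(n_samp)) {
      row <- amp[s, ]
      o <- offs[s] - 1L
      if (o > 0) row <- c(row[(o + 1):n_bins], row[1:o])
      g_null <- g_null + row
    }
    srt <- sort(g_null)
    # count of null values >= each observed G, via binary search
    exceed <- exceed + (n_bins - findInterval(g_obs, srt, left.open = TRUE))
    total <- total + n_bins
  })
  pvals <- (1 + exceed) / (1 + total)
  p.adjust(pvals, "BH")
}

call_peaks <- function(bins, direction, q_thresh) {
  q <- if (direction == "amp") bins$q_amp else bins$q_del
  g <- if (direction == "amp") bins$g_amp else bins$g_del
  sig <- q < q_thresh
  if (!any(sig)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), q = numeric(),
                      peak_bin_start = numeric(), stringsAsFactors = FALSE))
  }
  # maximal runs of significant bins within a chromosome
  run_id <- cumsum(c(TRUE, diff(which(sig)) > 1 |
                       bins$chrom[which(sig)][-1] != bins$chrom[which(sig)][-sum(sig)]))
  idx <- split(which(sig), run_id)
  do.call(rbind, lapply(idx, function(i) {
    data.frame(chrom = bins$chrom[i[1]],
               start = min(bins$start[i]), end = max(bins$end[i]),
               direction = direction, q = min(q[i]),
               peak_bin_start = bins$start[i[which.max(g[i])]],
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.GScoreProfile <- function(x, ...) {
  cat(sprintf("GScoreProfile: %d bins of %g bp, thresholds (%+g, %+g), %d peak(s) at q < %g\n",
              nrow(x$bins), x$bin_size, x$amp_thresh, x$del_thresh,
              nrow(x$peaks), x$q_thresh))
  invisible(x)
}
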