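test_that("arm-level calls follow the coverage threshold", {
  arms <- toy_genome_arms()
  # whole-arm gain at 1.5 on chr1p
  whole <- segment_table(data.frame(sample_id = "A", chrom = "chr1",
                                    start = 1, end = 5e7, value = 1.5))
  res <- arm_level(whole)
  expect_equal(res$gain_freq[res$arm == "chr1p"], 1)
  expect_equal(sum(res$gain_freq), 1)
  # 40% of the arm covered: below the 50% rule
  part <- segment_table(data.frame(sample_id = "A", chrom = "chr1",
                                   start = 1, end = 2e7, value = 1.5))
  expect_equal(arm_level(part)$gain_freq[1], 0)
  # losses are symmetric
  loss <- segment_table(data.frame(sample_id = "A", chrom = "chr2",
                                   start = 5e7 + 1, end = 1e8, value = -1.4))
  expect_equal(arm_level(loss)$loss_freq[4], 1)
})

test_that("planted arm frequency is recovered within 0.05 of the target", {
  cfg <- sim_config(n_samples = 300, seed = 31)
  sc <- simulate_cnv(cfg)
  res <- arm_level(sc$segments)
  expect_equal(res$gain_freq[res$arm == "chr2q"], 0.6, tolerance = 0.05)
  expect_equal(res$loss_freq[res$arm == "chr3p"], 0.5, tolerance = 0.05)
  # and matches the generator's own truth exactly
  expect_equal(res$gain_freq[res$arm == "chr2q"],
               mean(sc$truth$arm_events[, "chr2q"]))
})

test_that("G-score matches hand arithmetic and is fragmentation-invariant", {
  segs <- segment_table(data.frame(
    sample_id = c("A", "B", "C"), chrom = "chr1",
    start = 1, end = 1e6, value = c(2, 1.6, 0)))
  gp <- gscore(segs, n_perm = 0)
  expect_equal(gp$bins$g_amp[1], 3.6)
  expect_equal(gp$bins$g_del[1], 0)
  # splitting a qualifying segment into adjacent halves changes nothing
  frag <- segment_table(data.frame(
    sample_id = c("A", "A", "B", "C"), chrom = "chr1",
    start = c(1, 5e5 + 1, 1, 1), end = c(5e5, 1e6, 1e6, 1e6),
    value = c(2, 2, 1.6, 0)))
  gp2 <- gscore(frag, n_perm = 0)
  expect_equal(gp2$bins$g_amp, gp$bins$g_amp)
})

test_that("G-scores are invariant to sample order", {
  cfg <- sim_config(n_samples = 20, seed = 8)
  sc <- simulate_cnv(cfg)
  segs <- sc$segments
  shuf <- segs[order(rev(seq_len(nrow(segs)))), ]
  rownames(shuf) <- NULL
  class(shuf) <- class(segs)
  a <- gscore(segs, n_perm = 0)
  b <- gscore(shuf, n_perm = 0)
  expect_equal(a$bins$g_amp, b$bins$g_amp)
  expect_equal(a$bins$g_del, b$bins$g_del)
})

test_that("null data yields no peaks and planted focal events are called", {
  null_cfg <- sim_config(n_samples = 30, seed = 17,
                         planted_arm_events = data.frame(arm = character(),
                                                         effect = numeric(),
                                                         fraction = numeric()),
                         planted_focal_peaks = data.frame(chrom = character(),
                                                          start = numeric(),
                                                          end = numeric(),
                                                          effect = numeric(),
                                                          fraction = numeric()))
  null_segs <- simulate_cnv(null_cfg)$segments
  gp0 <- gscore(null_segs, n_perm = 200, seed = 1)
  expect_equal(nrow(gp0$peaks), 0L)
  # planted focal amplification called with small q
  cfg <- sim_config(n_samples = 60, seed = 18)
  gp <- gscore(simulate_cnv(cfg)$segments, n_perm = 500, seed = 2)
  amp_peaks <- gp$peaks[gp$peaks$direction == "amp", ]
  hit <- amp_peaks$chrom == "chr1" & amp_peaks$start <= 2e7 + 1 &
    amp_peaks$end >= 2.1e7
  expect_true(any(hit))
  expect_lt(min(amp_peaks$q[hit]), 0.05)
  # q-values are monotone non-increasing in G within a direction
  ord <- order(gp$bins$g_amp)
  expect_true(all(diff(gp$bins$q_amp[ord]) <= 1e-12))
})
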