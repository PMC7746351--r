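# Shared fixtures, built in code at test time.

options(tmescore.quiet = TRUE)

# tiny genes x samples expression TSV on disk; returns the path
write_tiny_expression <- function(lines = c("gene_id\tS1\tS2",
                                            "TP53\t10\t20",
                                            "GAPDH\t5\t15",
                                            "ACTB\t0\t3")) {
  path <- tempfile("expr", fileext = ".tsv")
  writeLines(lines, path)
  path
}

rc <- function(x) chartr("ACGT", "TGCA",
                         vapply(strsplit(x, NULL),
                                function(ch) paste(rev(ch), collapse = ""), ""))

# MutationTable drawn from a 96-category probability vector, with uniform
# random 41-mer flanks; optionally emitted on the purine strand
make_muts_from_probs <- function(p96, n_mut, sample_id = "S1", seed = 1,
                                 flip_strand = FALSE) {
  cats <- context_categories()
  set.seed(seed)
  idx <- sample.int(96, n_mut, replace = TRUE, prob = p96)
  f5 <- substr(cats[idx], 1, 1); ref <- substr(cats[idx], 3, 3)
  alt <- substr(cats[idx], 5, 5); f3 <- substr(cats[idx], 7, 7)
  rand <- function(n, l) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""), "")
  ctx3 <- paste0(f5, ref, f3)
  ctx41 <- paste0(rand(n_mut, 19), ctx3, rand(n_mut, 19))
  if (flip_strand) {
    ref <- chartr("ACGT", "TGCA", ref); alt <- chartr("ACGT", "TGCA", alt)
    ctx3 <- rc(ctx3); ctx41 <- rc(ctx41)
  }
  mutation_table(data.frame(
    sample_id = sample_id, chrom = "chr1", pos = seq_len(n_mut),
    ref = ref, alt = alt, variant_class = "Missense_Mutation",
    context = ctx3, context41 = ctx41, gene = "GENE001",
    stringsAsFactors = FALSE))
}

# catalogue from two disjoint-support signatures with separable exposures
# (pure samples for each signature), exactly factorizable
make_separable_catalogue <- function(seed = 1, n_samples = 30) {
  set.seed(seed)
  W <- matrix(0, 96, 2)
  W[1:48, 1] <- 1 / 48
  W[49:96, 2] <- 1 / 48
  H <- matrix(sample(50:300, 2 * n_samples, TRUE), 2, n_samples)
  H[2, 1:8] <- 0
  H[1, 9:16] <- 0
  cat96 <- t(W %*% H)
  dimnames(cat96) <- list(sprintf("S%02d", seq_len(n_samples)),
                          context_categories())
  list(catalogue = cat96, W = W, H = H)
}

# three well-separated Gaussian blobs in 2D
make_blobs <- function(n_per = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))))
  rownames(x) <- sprintf("I%02d", seq_len(3 * n_per))
  list(x = x, truth = rep(1:3, each = n_per))
}

# adjusted Rand index between two labelings (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
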