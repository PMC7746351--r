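test_that("catalogue collapses purine-strand records and tallies by hand", {
  # G>A at TGA is the reverse complement of C>T at TCA
  muts <- mutation_table(data.frame(
    sample_id = "S1", chrom = "chr1", pos = 1:10,
    ref = c("G", "C", "C", "A", "T", "C", "G", "C", "T", "A"),
    alt = c("A", "T", "T", "C", "G", "A", "T", "G", "C", "T"),
    variant_class = "Missense_Mutation",
    context = c("TGA", "TCA", "ACG", "CAG", "ATC", "CCA",
                "GGC", "TCT", "TTG", "TAT"),
    stringsAsFactors = FALSE))
  cat96 <- build_catalogue(muts)
  expect_equal(dim(cat96), c(1L, 96L))
  expect_equal(sum(cat96), 10)
  # hand tally after collapsing: G>A/TGA and C>T/TCA both -> T[C>T]A;
  # A>C/CAG -> C[T>G]G; G>T/GGC -> G[C>A]C; A>T/TAT -> A[T>A]A
  expect_equal(unname(cat96[1, "T[C>T]A"]), 2L)
  expect_equal(unname(cat96[1, "A[C>T]G"]), 1L)
  expect_equal(unname(cat96[1, "C[T>G]G"]), 1L)
  expect_equal(unname(cat96[1, "A[T>G]C"]), 1L)
  expect_equal(unname(cat96[1, "G[C>A]C"]), 1L)
  expect_equal(unname(cat96[1, "A[T>A]A"]), 1L)
})

test_that("catalogue tally matches an independent per-record collapse", {
  set.seed(1)
  muts <- make_muts_from_probs(rep(1 / 96, 96), 200, seed = 2,
                               flip_strand = FALSE)
  flipped <- make_muts_from_probs(rep(1 / 96, 96), 200, seed = 2,
                                  flip_strand = TRUE)
  a <- build_catalogue(muts)
  b <- build_catalogue(flipped)
  # strand collapsing is idempotent: flipping every record changes nothing
  expect_identical(a, b)
  expect_equal(sum(a), 200)
  # non-SNV records are skipped
  ind <- muts
  ind$ref[1] <- "AT"; ind$alt[1] <- "-"
  ind$variant_class[1] <- "Frame_Shift_Del"; ind$context[1] <- NA
  expect_equal(sum(build_catalogue(mutation_table(ind))), 199)
})

test_that("ARD NMF recovers a separable two-signature factorization exactly", {
  fx <- make_separable_catalogue(seed = 1)
  dec <- suppressWarnings(extract_signatures(fx$catalogue, n_restarts = 5,
                                             seed = 3))
  expect_equal(dec$k, 2L)
  cs <- vapply(1:2, function(j)
    max(apply(dec$W, 2, cosine_similarity, b = fx$W[, j])), 0)
  expect_true(all(cs >= 0.99))
  expect_equal(unname(colSums(dec$W)), rep(1, dec$k), tolerance = 1e-9)
  # reconstruction conserves the total mutation count up to prior shrinkage
  expect_equal(sum(dec$W %*% dec$H), sum(fx$catalogue), tolerance = 0.05)
})

test_that("a single-signature catalogue yields k = 1 proportional to truth", {
  set.seed(2)
  w <- rep(0, 96); w[sample.int(96, 12)] <- runif(12); w <- w / sum(w)
  H <- matrix(sample(100:300, 20, TRUE), 1, 20)
  cat96 <- t(sapply(H[1, ], function(h) h * w))   # 20 x 96: counts = H_j * w
  dimnames(cat96) <- list(sprintf("S%02d", 1:20), context_categories())
  dec <- suppressWarnings(extract_signatures(cat96, n_restarts = 5, seed = 4))
  expect_equal(dec$k, 1L)
  expect_gt(cosine_similarity(dec$W[, 1], w), 0.999)
})

test_that("cosine matching picks the right column with hand-checked values", {
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  ref <- synthetic_cosmic_reference()
  m <- cosine_match(ref[, c(4, 13), drop = FALSE], ref)
  expect_equal(m$best_match, c("Signature.4", "Signature.13"))
  expect_equal(m$cosine, c(1, 1), tolerance = 1e-12)
  # ties resolve to the lowest reference index
  tie_ref <- cbind(A = c(1, 0, 0), B = c(1, 0, 0), C = c(0, 1, 0))
  tm <- cosine_match(matrix(c(1, 0, 0), 3, 1,
                            dimnames = list(NULL, "q")), tie_ref)
  expect_equal(tm$best_match, "A")
})

test_that("exposure clustering separates pure-exposure samples deterministically", {
  set.seed(3)
  H <- cbind(matrix(c(100, 0, 0), 3, 8) + matrix(runif(24, 0, 5), 3, 8),
             matrix(c(0, 100, 0), 3, 8) + matrix(runif(24, 0, 5), 3, 8),
             matrix(c(0, 0, 100), 3, 8) + matrix(runif(24, 0, 5), 3, 8))
  rownames(H) <- paste0("Sig", 1:3)
  colnames(H) <- sprintf("S%02d", 1:24)
  ce <- cluster_exposures(H, k_range = 2:5, seed = 5)
  expect_equal(ce$k, 3L)
  truth <- rep(1:3, each = 8)
  expect_equal(length(unique(paste(ce$cluster, truth))), 3L)
  expect_setequal(ce$top_signature, paste0("Sig", 1:3))
  expect_identical(ce$cluster, cluster_exposures(H, k_range = 2:5, seed = 5)$cluster)
})

test_that("APOBEC enrichment matches the formula exactly on a designed fixture", {
  # window with exactly 1 TCW motif and 4 background cytosines:
  # E = (1/1) / (1/4) = 4
  win <- paste0("AAAAAAAAAAAAAAACCAA", "T", "C", "A", "CAAAAAAAAAAAAAAAAAA")
  expect_equal(nchar(win), 41L)
  muts <- mutation_table(data.frame(
    sample_id = "S1", chrom = "chr1", pos = 1:5, ref = "C", alt = "T",
    variant_class = "Missense_Mutation", context = "TCA", context41 = win,
    stringsAsFactors = FALSE))
  res <- apobec_enrichment(muts)
  expect_equal(res$enrichment, 4)
  expect_equal(res$class, "enriched")
  expect_equal(res$mut_tcw, 5L)
  expect_equal(res$context_tcw, 5L)
  expect_equal(res$context_c, 20L)
  # no TCW mutations: E = 0, non-enriched
  muts0 <- muts
  muts0$context <- "ACA"
  muts0$context41 <- paste0(strrep("A", 19), "ACA", strrep("A", 19))
  res0 <- apobec_enrichment(muts0)
  expect_equal(res0$enrichment, 0)
  expect_equal(res0$class, "non-enriched")
})

test_that("mutations drawn from background contexts are not APOBEC-enriched", {
  p <- rep(0, 96)
  cats <- context_categories()
  p[substr(cats, 3, 5) %in% c("C>T", "C>G")] <- 1 / 32   # uniform cytosine muts
  muts <- make_muts_from_probs(p, 400, seed = 6)
  res <- apobec_enrichment(muts)
  expect_lt(res$enrichment, 2)
  expect_gt(res$enrichment, 0.5)
  expect_equal(res$class, "non-enriched")
})

test_that("gene association test flags a gene confined to enriched samples", {
  apo <- data.frame(sample_id = sprintf("S%02d", 1:20),
                    enrichment = rep(c(5, 0.5), each = 10),
                    fisher_p = 0.5,
                    class = rep(c("enriched", "non-enriched"), each = 10))
  muts <- mutation_table(data.frame(
    sample_id = c(sprintf("S%02d", 1:9), sprintf("S%02d", c(2, 12, 15))),
    chrom = "chr1", pos = 1:12, ref = "C", alt = "T",
    variant_class = "Missense_Mutation",
    gene = rep(c("HOT", "COLD"), c(9, 3)), stringsAsFactors = FALSE))
  res <- apobec_gene_association(muts, apo)
  expect_equal(res$gene[1], "HOT")
  expect_lt(res$p[1], 0.05)
})

test_that("TMB counts non-silent records only", {
  muts <- mutation_table(data.frame(
    sample_id = rep(c("A", "B", "C"), c(25, 4, 0)),
    chrom = "chr1", pos = 1:29, ref = "C", alt = "T",
    variant_class = c(rep("Missense_Mutation", 15),
                      rep("Frame_Shift_Del", 4), rep("Silent", 6),
                      rep("Silent", 4)),
    stringsAsFactors = FALSE))
  tmb <- compute_tmb(muts)
  expect_equal(tmb$n_nonsilent[tmb$sample_id == "A"], 19L)
  expect_equal(tmb$tmb_per_mb[tmb$sample_id == "A"], 19 / 38)
  expect_equal(tmb$n_nonsilent[tmb$sample_id == "B"], 0L)   # silent-only
})
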