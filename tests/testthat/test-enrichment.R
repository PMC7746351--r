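test_that("ORA matches a hand-enumerated hypergeometric tail", {
  universe <- paste0("G", 1:10)
  sets <- gene_set_collection(list(S = paste0("G", 1:4)))
  query <- c("G1", "G2", "G5")
  res <- ora(query, sets, universe)
  # P(overlap >= 2) drawing 3 from 10 with 4 marked, by direct enumeration:
  # sum_{k=2}^{3} C(4,k) C(6,3-k) / C(10,3)
  p_hand <- (choose(4, 2) * choose(6, 1) + choose(4, 3) * choose(6, 0)) /
    choose(10, 3)
  expect_equal(res$p, p_hand)
  expect_equal(res$overlap, 2L)
  # disjoint query and set: overlap 0, p >= 0.5
  res0 <- ora(c("G9", "G10"), sets, universe)
  expect_equal(res0$overlap, 0L)
  expect_gte(res0$p, 0.5)
  # query outside the universe is an error
  expect_error(ora("NOPE", sets, universe), "universe")
})

test_that("a planted enriched set ranks first by FDR", {
  set.seed(1)
  universe <- paste0("G", 1:200)
  planted <- paste0("G", 1:20)
  sets <- gene_set_collection(c(
    list(planted = planted),
    setNames(lapply(1:5, function(i) sample(universe, 20)),
             paste0("rand", 1:5))))
  query <- c(paste0("G", 1:15), sample(setdiff(universe, planted), 5))
  res <- ora(query, sets, universe)
  expect_equal(res$set[1], "planted")
  expect_lt(res$fdr[1], 1e-6)
})

test_that("GSEA ES equals a hand-walked running sum on an 8-gene toy", {
  ranked <- setNames(c(4, 3, 2.5, 2, -1, -2, -3, -4), paste0("G", 1:8))
  set <- c("G1", "G3", "G8")
  res <- gsea(ranked, gene_set_collection(list(S = set)), n_perm = 50, seed = 1)
  # independent walk: hit increments |r|/sum(|r| in set), miss -1/(N - Nh)
  w <- abs(ranked); wsum <- sum(w[set])
  run <- 0; best <- 0
  for (g in names(ranked)) {
    run <- run + if (g %in% set) w[[g]] / wsum else -1 / 5
    if (abs(run) > abs(best)) best <- run
  }
  expect_equal(res$es, unname(best))
  # a set at the top of the ranking approaches ES = 1
  top <- gsea(ranked, gene_set_collection(list(S = c("G1", "G2", "G3"))),
              n_perm = 50, seed = 1)
  expect_gt(top$es, 0.8)
})

test_that("reversing the ranking negates the enrichment score", {
  set.seed(2)
  ranked <- setNames(rnorm(50), paste0("G", 1:50))
  sets <- gene_set_collection(list(S = paste0("G", c(1, 5, 9, 12, 20))))
  a <- gsea(sort(ranked, decreasing = TRUE), sets, n_perm = 20, seed = 1)
  b <- gsea(sort(-ranked, decreasing = TRUE), sets, n_perm = 20, seed = 1)
  expect_equal(a$es, -b$es)
})

test_that("a uniformly scattered set is not called enriched", {
  set.seed(3)
  ranked <- setNames(seq(5, -5, length.out = 100), paste0("G", 1:100))
  scattered <- paste0("G", seq(5, 95, by = 10))
  res <- gsea(ranked, gene_set_collection(list(S = scattered)),
              n_perm = 200, seed = 4)
  expect_lt(abs(res$es), 0.4)
  expect_gt(res$p, 0.05)
})

test_that("GSEA ES agrees with the fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  ranked <- setNames(rnorm(80), paste0("G", 1:80))
  set <- sample(names(ranked), 10)
  mine <- gsea(sort(ranked, decreasing = TRUE),
               gene_set_collection(list(S = set)), n_perm = 10, seed = 1)
  ref <- fgsea::calcGseaStat(sort(ranked, decreasing = TRUE),
                             which(names(sort(ranked, decreasing = TRUE)) %in% set),
                             gseaParam = 1)
  expect_equal(mine$es, ref, tolerance = 1e-9)
})

test_that("signal-to-noise metric orients group 1 minus group 2", {
  m <- rbind(up = c(5, 5, 5, 1, 1, 1), down = c(1, 1, 1, 5, 5, 5))
  colnames(m) <- paste0("S", 1:6)
  s2n <- signal_to_noise(m, rep(c("A", "B"), each = 3))
  expect_gt(s2n[["up"]], 0)
  expect_lt(s2n[["down"]], 0)
})
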