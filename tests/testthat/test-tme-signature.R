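test_that("random forest keeps a perfectly separating gene and is deterministic", {
  set.seed(1)
  n <- 60
  labels <- rep(c(1, 2), each = n / 2)
  m <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(paste0("G", 1:30), paste0("S", 1:n)))
  m["G7", ] <- ifelse(labels == 1, 0, 5) + rnorm(n, 0, 0.1)
  sig <- rf_reduce(m, labels, n_trees = 300, seed = 2)
  imp <- attr(sig, "importance")
  expect_equal(names(which.max(imp)), "G7")
  expect_true("G7" %in% sig)
  expect_identical(as.character(sig),
                   as.character(rf_reduce(m, labels, n_trees = 300, seed = 2)))
})

test_that("on pure noise the classifier cannot beat chance", {
  set.seed(2)
  n <- 60
  labels <- rep(1:3, each = n / 3)
  m <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("G", 1:40), paste0("S", 1:n)))
  sig <- rf_reduce(m, labels, n_trees = 300, seed = 3)
  expect_gt(attr(sig, "oob_error"), 0.4)   # chance error = 2/3
})

test_that("PC1 scores capture a rank-1 cluster exactly", {
  set.seed(3)
  profile <- rnorm(20)
  m <- outer(rep(1, 6), profile) * runif(6, 0.5, 2)   # perfectly correlated genes
  dimnames(m) <- list(paste0("G", 1:6), paste0("S", 1:20))
  gc <- setNames(rep(1, 6), rownames(m))
  res <- score_gene_clusters(m, gc)
  zprof <- as.vector(scale(profile))
  expect_equal(abs(cor(res$scores[, 1], zprof)), 1, tolerance = 1e-9)
  expect_equal(res$var_explained[[1]], 1, tolerance = 1e-9)
  expect_gte(sum(res$loadings[[1]]), 0)
  expect_equal(mean(res$scores[, 1]), 0, tolerance = 1e-9)
})

test_that("anti-correlated blocks give a contrast PC1 matching the eigen oracle", {
  set.seed(4)
  base <- rnorm(30)
  m <- rbind(G1 = base + rnorm(30, 0, 0.05),
             G2 = base + rnorm(30, 0, 0.05),
             G3 = -base + rnorm(30, 0, 0.05),
             G4 = -base + rnorm(30, 0, 0.05))
  colnames(m) <- paste0("S", 1:30)
  res <- score_gene_clusters(m, setNames(rep(1, 4), rownames(m)))
  z <- t(scale(t(m)))
  ev <- eigen(crossprod(t(z)))$vectors[, 1]   # gene-space PC1 via eigen
  if (sum(ev) < 0) ev <- -ev
  oracle_score <- as.vector(t(z) %*% ev)
  expect_equal(unname(res$scores[, 1]), oracle_score, tolerance = 1e-6)
  expect_gte(sum(res$loadings[[1]]), 0)
  # loadings oppose each other across the two blocks
  expect_lt(res$loadings[[1]][["G1"]] * res$loadings[[1]][["G3"]], 0)
})

test_that("TME score arithmetic and antisymmetry hold", {
  scores <- matrix(c(1, -1, 0.5, 2), 2, 2,
                   dimnames = list(c("S1", "S2"), c("GC1", "GC2")))
  dir <- c(GC1 = "favourable", GC2 = "unfavourable")
  expect_equal(compute_tme_score(scores, dir),
               c(S1 = 0.5, S2 = -3))
  flipped <- c(GC1 = "unfavourable", GC2 = "favourable")
  expect_equal(compute_tme_score(scores, flipped),
               -compute_tme_score(scores, dir))
  # no unfavourable clusters: plain sum
  dir2 <- c(GC1 = "favourable", GC2 = "favourable")
  expect_equal(compute_tme_score(scores, dir2), c(S1 = 1.5, S2 = 1))
  expect_error(compute_tme_score(scores, c(GC1 = "favourable")), "direction")
})

test_that("cluster directions follow the univariate Cox hazard", {
  set.seed(5)
  n <- 120
  good <- rnorm(n); bad <- rnorm(n)
  time <- rexp(n, rate = exp(-1 * good + 1 * bad) * 0.01)
  cl <- clinical_table(data.frame(sample_id = sprintf("S%03d", 1:n),
                                  os_time = time, os_event = 1))
  scores <- matrix(c(good, bad), n, 2,
                   dimnames = list(cl$sample_id, c("GC1", "GC2")))
  dir <- cluster_directions(scores, cl)
  expect_equal(as.character(dir), c("favourable", "unfavourable"))
  expect_lt(attr(dir, "hr")[["GC1"]], 1)
  expect_gt(attr(dir, "hr")[["GC2"]], 1)
})

test_that("maxstat statistics equal brute-force log-rank at every split", {
  set.seed(6)
  n <- 25
  score <- rnorm(n)
  time <- rexp(n, ifelse(score > 0, 2, 0.5))
  event <- rbinom(n, 1, 0.8)
  ms <- maxstat_cutpoint(score, time, event, n_perm = 0)
  for (i in seq_along(ms$candidates)) {
    g <- score > ms$candidates[i]
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(ms$z[i]^2, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("a planted survival split is recovered at the flanking order statistics", {
  set.seed(7)
  n <- 100
  score <- rnorm(n)
  time <- rexp(n, ifelse(score > 0, 0.1, 1))   # hazard ratio 10 at score 0
  ms <- maxstat_cutpoint(score, time, rep(1, n), n_perm = 0)
  lo <- max(score[score <= 0]); hi <- min(score[score > 0])
  expect_gte(ms$cutpoint, lo - 1e-12)
  expect_lt(ms$cutpoint, hi)
})

test_that("maxstat permutation p is calibrated under the null and reproducible", {
  set.seed(8)
  n <- 40
  time <- rexp(n); event <- rbinom(n, 1, 0.8)
  ps <- vapply(1:10, function(i) {
    score <- rnorm(n)   # independent of survival
    maxstat_cutpoint(score, time, event, n_perm = 100, seed = i)$p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.8)
  score <- rnorm(n)
  expect_identical(maxstat_cutpoint(score, time, event, n_perm = 50, seed = 3)$p,
                   maxstat_cutpoint(score, time, event, n_perm = 50, seed = 3)$p)
})

test_that("maxstat enforces sample and event preconditions", {
  expect_error(maxstat_cutpoint(rnorm(10), rexp(10), rep(1, 10)), "20 samples")
  expect_error(maxstat_cutpoint(rnorm(25), rexp(25), rep(0, 25)), "5 events")
})
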