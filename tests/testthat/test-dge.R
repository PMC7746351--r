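test_that("low-expression filter applies inclusive boundaries", {
  m <- rbind(zero = c(0, 0, 0, 0, 0),
             boundary = c(10, 0, 0, 0, 0),   # >= 10 in exactly 20% of samples
             below = c(9, 9, 9, 9, 9),
             high = c(50, 60, 70, 80, 90),
             sparse = c(11, 0, 0, 0, 0))
  colnames(m) <- paste0("S", 1:5)
  x <- expression_matrix(m, "counts")
  kept <- rownames(filter_low_expression(x, min_count = 10,
                                         min_samples_frac = 0.2))
  expect_equal(kept, c("BOUNDARY", "HIGH", "SPARSE"))
  expect_error(filter_low_expression(voom_transform(x)), "counts")
})

test_that("log-CPM transform matches its formula and is monotone", {
  m <- matrix(c(0, 999999), 2, 1, dimnames = list(c("A", "B"), "S1"))
  lc <- voom_transform(expression_matrix(m, "counts"))
  # count 0 at library size 1e6 - 1: log2((0 + 0.5) / 1e6 * 1e6) = -1
  expect_equal(unname(as.matrix(lc)["A", 1]), -1)
  expect_equal(unname(as.matrix(lc)["B", 1]),
               log2((999999 + 0.5) / 1e6 * 1e6))
  # doubling counts leaves log-CPM invariant up to the +0.5/+1 offsets
  set.seed(1)
  m2 <- matrix(rpois(200, 200), 20, 10,
               dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  l1 <- as.matrix(voom_transform(expression_matrix(m2, "counts")))
  l2 <- as.matrix(voom_transform(expression_matrix(2 * m2, "counts")))
  expect_equal(l1, l2, tolerance = 0.01)
  # monotone within a sample
  ord <- order(m2[, 1])
  expect_true(all(diff(l1[ord, 1]) >= 0))
})

test_that("moderated t with zero prior df reduces exactly to the pooled t", {
  set.seed(2)
  m <- matrix(rnorm(300 * 10, 8), 300, 10,
              dimnames = list(paste0("G", 1:300), paste0("S", 1:10)))
  g <- rep(c("A", "B"), each = 5)
  res <- moderated_t(m, g, prior_df = 0)
  oracle <- t(apply(m, 1, function(x) {
    tt <- t.test(x[1:5], x[6:10], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }))
  expect_equal(res$t, unname(oracle[, 1]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle[, 2]), tolerance = 1e-10)
  # infinite prior df gives a z-like test
  resz <- moderated_t(m, g, prior_df = Inf)
  expect_true(all(is.infinite(resz$df)))
})

test_that("moderated t agrees with the limma oracle on a fixture", {
  skip_if_not_installed("limma")
  set.seed(3)
  m <- matrix(rnorm(1000 * 8, 5, 1), 1000, 8,
              dimnames = list(paste0("G", 1:1000), paste0("S", 1:8)))
  m[1:40, 1:4] <- m[1:40, 1:4] + 2
  g <- rep(c("A", "B"), each = 4)
  res <- moderated_t(m, g)
  design <- stats::model.matrix(~ 0 + factor(g))
  colnames(design) <- c("A", "B")
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(m, design),
    limma::makeContrasts(A - B, levels = design)))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 0.01)
  expect_equal(res$t, unname(fit$t[, 1]), tolerance = 0.01)
  expect_equal(res$log2fc, unname(fit$coefficients[, 1]), tolerance = 1e-10)
})

test_that("variance moderation gains power over the ordinary t", {
  set.seed(4)
  n_genes <- 1500
  m <- matrix(rnorm(n_genes * 6, 0, 1), n_genes, 6,
              dimnames = list(paste0("G", 1:n_genes), paste0("S", 1:6)))
  de <- 1:150
  m[de, 1:3] <- m[de, 1:3] + 1.5
  g <- rep(c("A", "B"), each = 3)
  p_mod <- moderated_t(m, g)$p[de]
  p_ord <- moderated_t(m, g, prior_df = 0)$p[de]
  expect_lt(median(p_mod), median(p_ord))
})

test_that("significance rule needs both the p and fold-change thresholds", {
  set.seed(5)
  base <- matrix(rnorm(40 * 10, 0, 0.05), 40, 10,
                 dimnames = list(paste0("G", 1:40), paste0("S", 1:10)))
  base["G1", 6:10] <- base["G1", 6:10] + 2.5   # large shift, tiny noise
  base["G2", 6:10] <- base["G2", 6:10] + 0.5   # sub-threshold shift, tiny p
  g <- rep(c("A", "B"), each = 5)
  res <- moderated_t(base, g)
  expect_true(res$significant[res$gene == "G1"])
  expect_lt(res$p[res$gene == "G2"], 1e-6)
  expect_false(res$significant[res$gene == "G2"])
  expect_equal(res$significant, res$p < 1e-3 & abs(res$log2fc) > 1)
})

test_that("swapping group labels negates the statistic but not p", {
  set.seed(6)
  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(paste0("G", 1:100), paste0("S", 1:8)))
  g <- rep(c("A", "B"), each = 4)
  a <- moderated_t(m, factor(g, levels = c("A", "B")))
  b <- moderated_t(m, factor(g, levels = c("B", "A")))
  expect_equal(a$t, -b$t)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("common-DEG rules count contrasts correctly", {
  mk <- function(genes, sig) {
    r <- data.frame(gene = genes, log2fc = 2, mean_expr = 1, t = 5,
                    df = 10, p = 1e-5, fdr = 1e-4, significant = sig)
    class(r) <- c("DGEResult", "data.frame")
    r
  }
  res <- list(`1v2` = mk(c("A", "B", "C"), c(TRUE, TRUE, FALSE)),
              `2v3` = mk(c("A", "B", "C"), c(TRUE, FALSE, FALSE)),
              `1v3` = mk(c("A", "B", "C"), c(TRUE, FALSE, TRUE)))
  # counts: A in 3 contrasts, B and C in 1 each
  expect_equal(deg_intersection(res, "all"), "A")
  expect_equal(deg_intersection(res, "two"), "A")
  expect_setequal(deg_intersection(res, "any"), c("A", "B", "C"))
  res$`2v3`$significant <- c(TRUE, TRUE, FALSE)   # B now in 2 contrasts
  expect_setequal(deg_intersection(res, "two"), c("A", "B"))
})
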