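test_that("KM with no censoring steps through the empirical survival", {
  time <- c(2, 5, 7, 9, 12)
  km <- km_fit(time, rep(1, 5))
  expect_equal(km[["all"]]$time, time)
  expect_equal(km[["all"]]$surv, (4:0) / 5)
  # probabilities non-increasing from 1
  expect_true(all(diff(km[["all"]]$surv) <= 0))
})

test_that("log-rank matches brute-force risk-set arithmetic on a textbook fixture", {
  time <- c(6, 7, 10, 15, 19, 25, 1, 3, 5, 8, 12, 17)
  event <- rep(1, 12)
  group <- rep(c("A", "B"), each = 6)
  lr <- logrank_test(time, event, group)
  # independent oracle: accumulate O - E and V over the risk table
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == "A")
    n <- sum(at_risk); n1 <- sum(at_risk & group == "A")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chisq, o_minus_e^2 / v, tolerance = 1e-9)
  expect_equal(lr$df, 1)
  # identical groups: chi-square ~ 0
  lr0 <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("A", "B"), each = 12))
  expect_lt(lr0$chisq, 1e-9)
})

test_that("Cox fit recovers a known hazard ratio and flags degeneracies", {
  set.seed(1)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = 0.01 * 2^x)
  cens <- rexp(n, rate = 0.003)
  fit <- cox_fit(pmin(time, cens), as.integer(time <= cens), data.frame(x = x))
  expect_gt(fit$hr[["x"]], 1.7)
  expect_lt(fit$hr[["x"]], 2.3)
  expect_true(fit$ci_lower[["x"]] < fit$hr[["x"]],
              fit$hr[["x"]] < fit$ci_upper[["x"]])
  expect_equal(unname(exp(fit$coef)), unname(fit$hr))
  # null covariate: small |z|
  fit0 <- cox_fit(pmin(time, cens), as.integer(time <= cens),
                  data.frame(z = rnorm(n)))
  expect_lt(abs(fit0$z[[1]]), 3)
  # exact collinearity is an error
  expect_error(cox_fit(pmin(time, cens), as.integer(time <= cens),
                       data.frame(a = x, b = x)), "singular")
})

test_that("Cox score test equals the log-rank chi-square on two-group data", {
  set.seed(2)
  for (i in 1:3) {
    n <- 60
    g <- rbinom(n, 1, 0.5)
    time <- rexp(n, 0.1 * 1.8^g)
    event <- rbinom(n, 1, 0.9)
    fit <- cox_fit(time, event, data.frame(g = g))
    lr <- logrank_test(time, event, g)
    expect_equal(fit$score_chisq, lr$chisq, tolerance = 1e-6)
  }
})

test_that("cell network finds the planted driver and correlation edges", {
  set.seed(3)
  n <- 150
  f <- matrix(rgamma(n * 5, 2), n, 5)
  f <- f / rowSums(f)
  colnames(f) <- paste0("CT", 1:5)
  rownames(f) <- sprintf("S%03d", 1:n)
  # CT1 abundance drives hazard
  time <- rexp(n, rate = 0.01 * exp(6 * f[, 1]))
  cl <- clinical_table(data.frame(sample_id = rownames(f),
                                  os_time = time, os_event = 1))
  net <- cell_network(f, cl)
  imp <- net$impact
  expect_equal(imp$cell_type[which.max(imp$impact)], "CT1")
  expect_equal(imp$direction[imp$cell_type == "CT1"], "risk")
  # duplicated column gives a rho = 1 edge
  f2 <- cbind(f, CT6 = f[, 2])
  net2 <- cell_network(f2, cl)
  e <- net2$edges
  expect_true(any(e$from == "CT2" & e$to == "CT6" & abs(e$rho - 1) < 1e-12))
  # constant column is dropped from edges with a warning
  f3 <- cbind(f, CT7 = 0.1)
  expect_warning(net3 <- cell_network(f3, cl), "constant")
  expect_false(any(c(net3$edges$from, net3$edges$to) == "CT7"))
})

test_that("AUC equals the exhaustive concordant-pair fraction and is rank-invariant", {
  score <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.2)
  outcome <- c(0, 0, 1, 1, 0, 1)
  # brute force over all case-control pairs (+1 concordant, +0.5 tie)
  cases <- which(outcome == 1); controls <- which(outcome == 0)
  tot <- 0
  for (i in cases) for (j in controls)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  expect_equal(roc_auc(score, outcome), tot / (length(cases) * length(controls)))
  # perfect separation and null behaviour
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(4)
  expect_equal(roc_auc(rnorm(4000), rbinom(4000, 1, 0.5)), 0.5, tolerance = 0.05)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(score), outcome), roc_auc(score, outcome))
})

test_that("DeLong comparison returns a calibrated two-sided p", {
  set.seed(5)
  n <- 300
  outcome <- rbinom(n, 1, 0.5)
  s1 <- outcome + rnorm(n)        # informative
  s2 <- rnorm(n)                  # noise
  cmp <- delong_compare(s1, s2, outcome)
  expect_gt(cmp$auc1, cmp$auc2)
  expect_lt(cmp$p, 0.01)
  expect_equal(cmp$delta_auc, cmp$auc1 - cmp$auc2)
})
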