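# Survival statistics and biomarker comparison: Kaplan-Meier curves,
# log-rank tests and Cox proportional-hazards fits (via the survival
# package, Breslow tie handling), the cell interaction network (per-cell
# survival impact from median-split log-rank plus Spearman correlation
# edges), and ROC/AUC with DeLong comparison (via pROC).

#' Kaplan-Meier curves per group
#'
#' @param time,event survival outcome (event 0/1).
#' @param groups optional group label per sample (single group if NULL).
#' @return A list of class `KMCurve`, one element per group, each with
#'   `time`, `surv`, `n_risk`, `n_event`, `n_censor`.
#' @export
km_fit <- function(time, event, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(time))
  fit <- survfit(Surv(time, event) ~ g,
                 data = data.frame(time = time, event = event, g = factor(groups)))
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), "g=all") else fit$strata
  idx <- rep(seq_along(strata), strata)
  out <- lapply(seq_along(strata), function(i) {
    sel <- idx == i
    list(time = fit$time[sel], surv = fit$surv[sel],
         n_risk = fit$n.risk[sel], n_event = fit$n.event[sel],
         n_censor = fit$n.censor[sel])
  })
  names(out) <- sub("^g=", "", names(strata))
  structure(out, class = "KMCurve")
}

#' Log-rank test
#'
#' @param time,event survival outcome.
#' @param groups group label per sample.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  sd <- survdiff(Surv(time, event) ~ g,
                 data = data.frame(time = time, event = event, g = factor(groups)))
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Breslow tie handling; Newton-Raphson via the survival package with a
#' tight convergence tolerance. Exactly collinear covariates are an error;
#' monotone likelihood (perfect separation) is flagged, with estimates at
#' the iteration cap.
#'
#' @param time,event survival outcome.
#' @param covariates data.frame (or vector) of covariates.
#' @return A list of class `CoxFit`: `coef` (log-HR), `hr`, `ci_lower`,
#'   `ci_upper` (95%), `se`, `z`, `p` (Wald), `loglik`, `score_chisq`
#'   (global score test), `converged`, `flagged` (infinite-coefficient
#'   warning).
#' @export
cox_fit <- function(time, event, covariates) {
  if (!is.data.frame(covariates))
    covariates <- data.frame(x = covariates)
  dat <- data.frame(.time = time, .event = event, covariates,
                    check.names = TRUE)
  flagged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = dat, ties = "breslow",
          control = coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (anyNA(fit$coefficients))
    stop("singular information matrix (collinear covariates): ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", "))
  s <- summary(fit)
  nm <- names(fit$coefficients)
  col <- function(m, j) setNames(m[, j], nm)
  structure(list(coef = fit$coefficients,
                 hr = exp(fit$coefficients),
                 ci_lower = col(s$conf.int, "lower .95"),
                 ci_upper = col(s$conf.int, "upper .95"),
                 se = col(s$coefficients, "se(coef)"),
                 z = col(s$coefficients, "z"),
                 p = col(s$coefficients, "Pr(>|z|)"),
                 loglik = fit$loglik[2],
                 score_chisq = unname(s$sctest["test"]),
                 converged = fit$iter < 50,
                 flagged = flagged),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat("CoxFit:\n")
  print(data.frame(HR = round(x$hr, 3),
                   `95% CI` = sprintf("%.3f-%.3f", x$ci_lower, x$ci_upper),
                   p = signif(x$p, 3), check.names = FALSE))
  invisible(x)
}

#' Tumor-immune cell interaction network
#'
#' Per cell type, the survival impact is -log10 of the log-rank p-value of
#' the split at the abundance quantile (median by default), signed as
#' `"risk"` when the high-abundance group has worse survival and
#' `"favourable"` otherwise. Edges are pairwise Spearman correlations
#' between cell fractions, retained when |rho| >= `rho_min` and
#' p < `p_max`. Constant fraction columns yield undefined ranks and are
#' dropped from edges with a warning.
#'
#' @param fractions `CellFractions` (or samples x types matrix).
#' @param clinical `ClinicalTable` covering the samples.
#' @param split_quantile abundance split point.
#' @param rho_min,p_max edge retention thresholds.
#' @return A list of class `CellNetwork`: `impact` (data.frame cell_type,
#'   impact, direction, logrank_p), `edges` (data.frame from, to, rho, p).
#' @export
cell_network <- function(fractions, clinical, split_quantile = 0.5,
                         rho_min = 0.2, p_max = 0.05) {
  f <- if (inherits(fractions, "CellFractions")) fractions$fractions else as.matrix(fractions)
  idx <- match(rownames(f), clinical$sample_id)
  if (anyNA(idx)) stop("clinical data missing for some samples")
  time <- clinical$os_time[idx]; event <- clinical$os_event[idx]
  impact <- do.call(rbind, lapply(colnames(f), function(ct) {
    v <- f[, ct]
    cut <- quantile(v, split_quantile)
    hi <- v > cut
    if (length(unique(hi)) < 2)
      return(data.frame(cell_type = ct, impact = 0, direction = NA,
                        logrank_p = NA, stringsAsFactors = FALSE))
    lr <- logrank_test(time, event, hi)
    # sign: risk if the high-abundance group carries the higher hazard
    worse_high <- coxph(Surv(time, event) ~ hi,
                        ties = "breslow")$coefficients[[1]] > 0
    data.frame(cell_type = ct, impact = -log10(lr$p),
               direction = if (worse_high) "risk" else "favourable",
               logrank_p = lr$p, stringsAsFactors = FALSE)
  }))
  const <- apply(f, 2, function(v) sd(v) == 0)
  if (any(const))
    warning("constant fraction column(s) dropped from edges: ",
            paste(colnames(f)[const], collapse = ", "))
  use <- colnames(f)[!const]
  edges <- NULL
  if (length(use) >= 2) {
    pairs <- utils::combn(use, 2)
    edges <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      ct <- suppressWarnings(cor.test(f[, pairs[1, i]], f[, pairs[2, i]],
                                      method = "spearman"))
      data.frame(from = pairs[1, i], to = pairs[2, i],
                 rho = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
    edges <- edges[abs(edges$rho) >= rho_min & edges$p < p_max, , drop = FALSE]
  }
  structure(list(impact = impact, edges = edges), class = "CellNetwork")
}

#' ROC AUC of a score against a binary outcome
#'
#' Mann-Whitney AUC with tie correction, equal to the fraction of
#' concordant pairs plus half the ties.
#'
#' @param score continuous marker.
#' @param outcome binary outcome (0/1 or logical).
#' @return scalar AUC (orientation: larger score predicts outcome 1).
#' @export
roc_auc <- function(score, outcome) {
  outcome <- as.integer(as.logical(outcome))
  r <- suppressMessages(roc(outcome, score, direction = "<", quiet = TRUE))
  as.numeric(auc(r))
}

#' DeLong comparison of two paired ROC curves
#'
#' @param score1,score2 two markers measured on the same samples.
#' @param outcome shared binary outcome.
#' @return list with `auc1`, `auc2`, `delta_auc`, `z`, `p`.
#' @export
delong_compare <- function(score1, score2, outcome) {
  outcome <- as.integer(as.logical(outcome))
  r1 <- suppressMessages(roc(outcome, score1, direction = "<", quiet = TRUE))
  r2 <- suppressMessages(roc(outcome, score2, direction = "<", quiet = TRUE))
  tst <- roc.test(r1, r2, method = "delong", paired = TRUE)
  list(auc1 = as.numeric(auc(r1)), auc2 = as.numeric(auc(r2)),
       delta_auc = as.numeric(auc(r1)) - as.numeric(auc(r2)),
       z = unname(tst$statistic), p = tst$p.value)
}
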