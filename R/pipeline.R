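# Pipeline orchestration: run the full workflow from one configuration,
# writing per-stage TSV outputs and a JSON run manifest with seeds,
# parameters, file hashes and wall times.

# Stable 32-bit hash of a string (polynomial rolling hash in double
# arithmetic), used to derive per-stage seeds from the master seed so that
# adding stages never perturbs existing ones.
string_hash32 <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Per-stage seed derivation
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(master_seed, stage) {
  as.integer((as.numeric(master_seed) + string_hash32(stage)) %% 2147483647)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its own seed from it via
#'   [stage_seed()].
#' @param n_samples cohort size for the simulate stage.
#' @param out_dir output directory.
#' @param n_resamples consensus resamples.
#' @param deconv_perms deconvolution permutations (0 skips p-values).
#' @param nmf_restarts NMF restarts.
#' @param cnv_perms cyclic permutations for G-score q-values.
#' @param stages stages to run, in order.
#' @return named list.
#' @export
pipeline_config <- function(seed = 1L, n_samples = 300, out_dir = "tmescore_run",
                            n_resamples = 1000, deconv_perms = 0,
                            nmf_restarts = 20, cnv_perms = 1000,
                            stages = c("simulate", "deconvolve", "cluster",
                                       "dge", "tmescore", "survival",
                                       "enrichment", "mutsig", "cnv")) {
  list(seed = as.integer(seed), n_samples = n_samples, out_dir = out_dir,
       n_resamples = n_resamples, deconv_perms = deconv_perms,
       nmf_restarts = nmf_restarts, cnv_perms = cnv_perms, stages = stages)
}

#' Run the full workflow
#'
#' Executes the configured stages in dependency order on a synthetic cohort:
#' simulate, deconvolve, consensus-cluster the cell fractions, differential
#' expression between the clusters, TME signature/score with its prognostic
#' cutpoint, survival and ROC summaries, over-representation of the
#' signature genes against cell-type marker sets, mutational signatures
#' with APOBEC enrichment and TMB, and G-score CNV peaks. Writes TSV
#' outputs plus `manifest.json` under `out_dir` and aborts with the stage
#' name on failure.
#'
#' @param config list from [pipeline_config()] or a path to a YAML file of
#'   the same fields.
#' @return A list of class `RunManifest`: `config`, `stage_seeds`,
#'   `outputs` (per stage: files, md5 hashes, seconds), `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- utils::modifyList(pipeline_config(),
                                                        read_yaml(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  manifest <- list(config = config[setdiff(names(config), "stages")],
                   stages_run = config$stages,
                   package_version = as.character(packageVersion("tmescore")),
                   stage_seeds = list(), outputs = list())
  summary <- list()
  for (stage in config$stages) {
    seed <- stage_seed(config$seed, stage)
    manifest$stage_seeds[[stage]] <- seed
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(
      run_stage(stage, config, seed, state, summary_env = state),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    secs <- proc.time()[["elapsed"]] - t0
    manifest$outputs[[stage]] <- list(
      files = files, md5 = as.list(md5sum(files)), seconds = round(secs, 2))
    tme_log("stage %-10s done in %.1fs", stage, secs)
  }
  manifest$summary <- state$summary
  write_json(manifest, file.path(config$out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  structure(manifest, class = "RunManifest")
}

run_stage <- function(stage, config, seed, st, summary_env) {
  out <- function(...) file.path(config$out_dir, ...)
  add_summary <- function(...) {
    st$summary <- utils::modifyList(if (is.null(st$summary)) list() else st$summary,
                                    list(...))
  }
  switch(stage,
    simulate = {
      st$simcfg <- sim_config(n_samples = config$n_samples, seed = seed)
      st$cohort <- simulate_cohort(st$simcfg)
      st$mut <- simulate_mutations(st$simcfg)
      st$cnv <- simulate_cnv(st$simcfg)
      write_expression(st$cohort$expression, out("expression.tsv"))
      write_tsv(st$cohort$clinical, out("clinical.tsv"))
      write_tsv(st$mut$mutations, out("mutations.tsv"))
      write_tsv(st$cnv$segments, out("segments.tsv"))
      # marker gene sets of the bundled reference double as a toy GMT
      st$gmt <- marker_gene_sets(st$simcfg$reference)
      write_gmt(st$gmt, out("gene_sets.gmt"))
      add_summary(n_samples = config$n_samples)
      c(out("expression.tsv"), out("clinical.tsv"), out("mutations.tsv"),
        out("segments.tsv"), out("gene_sets.gmt"))
    },
    deconvolve = {
      st$fractions <- deconvolve(st$cohort$expression, st$simcfg$reference,
                                 n_permutations = config$deconv_perms,
                                 seed = seed)
      write_fractions(st$fractions, out("cell_fractions.tsv"))
      out("cell_fractions.tsv")
    },
    cluster = {
      st$clust <- consensus_cluster(st$fractions$fractions,
                                    n_resamples = config$n_resamples,
                                    seed = seed)
      write_tsv(data.frame(sample_id = names(st$clust$final_labels),
                           cluster = st$clust$final_labels),
                out("tme_clusters.tsv"))
      add_summary(chosen_k = st$clust$chosen_k,
                  cluster_sizes = as.list(table(st$clust$final_labels)))
      out("tme_clusters.tsv")
    },
    dge = {
      filt <- filter_low_expression(st$cohort$expression)
      st$logcpm <- voom_transform(filt)
      st$dge <- pairwise_moderated_t(st$logcpm, st$clust$final_labels)
      st$degs <- deg_intersection(st$dge)
      for (nm in names(st$dge))
        write_tsv(st$dge[[nm]], out(paste0("dge_", nm, ".tsv")))
      writeLines(st$degs, out("common_degs.txt"))
      add_summary(deg_counts = lapply(st$dge, function(r) sum(r$significant)),
                  n_common_degs = length(st$degs))
      c(vapply(names(st$dge), function(nm) out(paste0("dge_", nm, ".tsv")), ""),
        out("common_degs.txt"))
    },
    tmescore = {
      st$tme <- build_tme_score(st$logcpm, st$degs, st$clust$final_labels,
                                st$cohort$clinical,
                                n_resamples = min(config$n_resamples, 200),
                                seed = seed)
      write_tsv(data.frame(sample_id = names(st$tme$tme_score),
                           tme_score = st$tme$tme_score,
                           group = st$tme$group), out("tme_score.tsv"))
      writeLines(st$tme$signature_genes, out("signature_genes.txt"))
      add_summary(n_signature_genes = length(st$tme$signature_genes),
                  tme_cutpoint = st$tme$cutpoint,
                  tme_groups = as.list(table(st$tme$group)))
      c(out("tme_score.tsv"), out("signature_genes.txt"))
    },
    survival = {
      cl <- st$cohort$clinical
      idx <- match(names(st$tme$tme_score), cl$sample_id)
      lr <- logrank_test(cl$os_time[idx], cl$os_event[idx], st$tme$group)
      cox <- cox_fit(cl$os_time[idx], cl$os_event[idx],
                     data.frame(low_group = as.integer(st$tme$group == "low")))
      net <- cell_network(st$fractions, cl)
      write_tsv(net$impact, out("cell_impact.tsv"))
      if (!is.null(net$edges)) write_tsv(net$edges, out("cell_edges.tsv"))
      auc_tme <- roc_auc(st$tme$tme_score, cl$response[idx])
      tmb <- compute_tmb(st$mut$mutations)
      tidx <- match(cl$sample_id[idx], tmb$sample_id)
      cmp <- delong_compare(st$tme$tme_score, tmb$tmb_per_mb[tidx],
                            cl$response[idx])
      add_summary(logrank_p = lr$p, cox_hr_low_vs_high = unname(cox$hr),
                  auc_tme = cmp$auc1, auc_tmb = cmp$auc2,
                  auc_delong_p = cmp$p)
      c(out("cell_impact.tsv"),
        if (!is.null(net$edges)) out("cell_edges.tsv"))
    },
    enrichment = {
      res <- ora(intersect(st$tme$signature_genes, rownames(st$logcpm)),
                 st$gmt, rownames(st$logcpm))
      write_tsv(res, out("ora.tsv"))
      rk <- signal_to_noise(st$logcpm,
                            factor(st$tme$group, levels = c("high", "low")))
      gs <- gsea(rk, st$gmt, n_perm = 200, seed = seed)
      write_tsv(gs, out("gsea.tsv"))
      add_summary(top_ora_set = res$set[1])
      c(out("ora.tsv"), out("gsea.tsv"))
    },
    mutsig = {
      cat96 <- build_catalogue(st$mut$mutations)
      write_tsv(data.frame(sample_id = rownames(cat96), cat96,
                           check.names = FALSE), out("catalogue96.tsv"))
      dec <- extract_signatures(cat96, n_restarts = config$nmf_restarts,
                                seed = seed)
      write_tsv(data.frame(category = rownames(dec$W), dec$W,
                           check.names = FALSE), out("signatures_W.tsv"))
      write_tsv(data.frame(signature = rownames(dec$H), dec$H,
                           check.names = FALSE), out("exposures_H.tsv"))
      apo <- apobec_enrichment(st$mut$mutations)
      write_tsv(apo, out("apobec.tsv"))
      add_summary(nmf_k = dec$k,
                  apobec_enriched = sum(apo$class == "enriched"),
                  best_matches = if (!is.null(dec$match)) as.list(
                    setNames(dec$match$best_match, dec$match$signature)))
      c(out("catalogue96.tsv"), out("signatures_W.tsv"),
        out("exposures_H.tsv"), out("apobec.tsv"))
    },
    cnv = {
      gp <- gscore(st$cnv$segments, n_perm = config$cnv_perms, seed = seed)
      write_tsv(gp$bins, out("gscore_bins.tsv"))
      write_tsv(gp$arm_table, out("arm_frequencies.tsv"))
      write_tsv(gp$peaks, out("cnv_peaks.tsv"))
      add_summary(n_cnv_peaks = nrow(gp$peaks))
      c(out("gscore_bins.tsv"), out("arm_frequencies.tsv"), out("cnv_peaks.tsv"))
    },
    stop("unknown stage: ", stage))
}

# Marker gene sets derived from a block reference: for each cell type, the
# genes whose profile in that type exceeds 5x their median across types.
marker_gene_sets <- function(reference) {
  R <- as.matrix(reference)
  med <- apply(R, 1, median)
  sets <- lapply(colnames(R), function(ct) rownames(R)[R[, ct] > 5 * med])
  names(sets) <- gsub("[^A-Za-z0-9]+", "_", colnames(R))
  gene_set_collection(sets[vapply(sets, length, 1L) > 0])
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest:", length(x$outputs), "stage(s) run\n")
  utils::str(x$summary, max.level = 1)
  invisible(x)
}
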