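# Synthetic cohort generator. Emulates the statistical structure the
# downstream stages assume: bulk expression as a noisy mixture of cell-type
# reference profiles under a small number of planted infiltration patterns,
# survival times whose hazard depends on the pattern, mutation catalogues
# drawn from planted 96-context signatures (one APOBEC-like), and segment
# tables with planted arm-level and focal copy-number events.

#' Simulation configuration
#'
#' Builds the configuration driving all synthetic generators. Defaults define
#' the package's reference study conditions: 300 samples, three infiltration
#' patterns (each concentrating Dirichlet mass on a distinct block of cell
#' types), negative-binomial counts with gene-level dispersion 0.1,
#' exponential survival with pattern hazard ratios (0.5, 1, 2) and ~30%
#' censoring, three mutational signatures (one concentrating >= 80% of its
#' mass on T[C>T]W / T[C>G]W), and planted arm-level (+/-1.5) and focal
#' (+/-2) copy-number events on a toy 4-chromosome genome.
#'
#' @param n_samples cohort size.
#' @param n_patterns number of planted infiltration patterns.
#' @param reference `SignatureMatrixRef` mixed to produce expression.
#' @param dirichlet_alpha patterns x cell-types matrix of Dirichlet
#'   concentrations; default gives each pattern a block of favoured types
#'   (alpha 4) over a 0.25 baseline.
#' @param library_size_mean,library_size_cv log-normal library-size model.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param hazard_ratios per-pattern hazard ratios (length `n_patterns`).
#' @param baseline_median_days median overall survival under hazard ratio 1.
#' @param censoring_rate target fraction of censored samples.
#' @param response_prob per-pattern probability of the binary response flag.
#' @param n_mut_signatures number of planted mutational signatures (>= 1;
#'   signature 1 is always the APOBEC-like TCW-concentrated one).
#' @param tcw_mass mass the APOBEC-like signature places on T[C>T]W/T[C>G]W.
#' @param mutations_per_sample integer range (min, max) of SNV counts.
#' @param exposure_alpha Dirichlet concentration for per-sample signature
#'   exposures.
#' @param indel_fraction fraction of extra non-SNV (indel) records appended.
#' @param silent_fraction fraction of SNVs labelled Silent.
#' @param planted_arm_events data.frame `arm`, `effect`, `fraction`.
#' @param planted_focal_peaks data.frame `chrom`, `start`, `end`, `effect`,
#'   `fraction`.
#' @param background_sd SD of background segment values.
#' @param seed mandatory integer seed; every generator is a pure function of
#'   the configuration including the seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_samples = 300,
                       n_patterns = 3,
                       reference = synthetic_lm22(),
                       dirichlet_alpha = NULL,
                       library_size_mean = 2e5,
                       library_size_cv = 0.15,
                       nb_dispersion = 0.1,
                       hazard_ratios = c(0.5, 1, 2),
                       baseline_median_days = 1095,
                       censoring_rate = 0.3,
                       response_prob = c(0.6, 0.4, 0.2),
                       n_mut_signatures = 3,
                       tcw_mass = 0.9,
                       mutations_per_sample = c(50, 200),
                       exposure_alpha = 1,
                       indel_fraction = 0.05,
                       silent_fraction = 0.1,
                       planted_arm_events = data.frame(
                         arm = c("chr2q", "chr3p"),
                         effect = c(1.5, -1.5),
                         fraction = c(0.6, 0.5),
                         stringsAsFactors = FALSE),
                       planted_focal_peaks = data.frame(
                         chrom = c("chr1", "chr4"),
                         start = c(2e7 + 1, 7e7 + 1),
                         end = c(2.1e7, 7.1e7),
                         effect = c(2, -2),
                         fraction = c(0.4, 0.3),
                         stringsAsFactors = FALSE),
                       background_sd = 0.1,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  n_types <- ncol(reference)
  if (is.null(dirichlet_alpha)) {
    # Each pattern favours a contiguous block of cell types so that every
    # cell type is strongly represented in exactly one pattern.
    dirichlet_alpha <- matrix(0.25, n_patterns, n_types,
                              dimnames = list(NULL, colnames(reference)))
    blocks <- split(seq_len(n_types),
                    cut(seq_len(n_types), n_patterns, labels = FALSE))
    for (k in seq_len(n_patterns)) dirichlet_alpha[k, blocks[[k]]] <- 4
  }
  stopifnot(nrow(dirichlet_alpha) == n_patterns,
            ncol(dirichlet_alpha) == n_types,
            all(dirichlet_alpha > 0),
            length(hazard_ratios) == n_patterns,
            all(hazard_ratios > 0),
            length(response_prob) == n_patterns,
            censoring_rate > 0, censoring_rate < 1,
            library_size_mean > 0, library_size_cv > 0, nb_dispersion > 0,
            n_mut_signatures >= 1,
            length(mutations_per_sample) == 2,
            mutations_per_sample[1] <= mutations_per_sample[2])
  structure(list(
    n_samples = n_samples, n_patterns = n_patterns, reference = reference,
    dirichlet_alpha = dirichlet_alpha,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    nb_dispersion = nb_dispersion, hazard_ratios = hazard_ratios,
    baseline_median_days = baseline_median_days,
    censoring_rate = censoring_rate, response_prob = response_prob,
    n_mut_signatures = n_mut_signatures, tcw_mass = tcw_mass,
    mutations_per_sample = mutations_per_sample,
    exposure_alpha = exposure_alpha, indel_fraction = indel_fraction,
    silent_fraction = silent_fraction,
    planted_arm_events = planted_arm_events,
    planted_focal_peaks = planted_focal_peaks,
    background_sd = background_sd, seed = as.integer(seed)),
    class = "SimConfig")
}

rdirichlet_rows <- function(alpha_matrix) {
  g <- matrix(rgamma(length(alpha_matrix), shape = alpha_matrix),
              nrow(alpha_matrix), ncol(alpha_matrix))
  g / rowSums(g)
}

#' Simulate a bulk expression cohort with survival
#'
#' Draws per-sample cell fractions from the pattern-specific Dirichlet,
#' mixes the reference profiles, adds negative-binomial noise at the
#' configured library size, and draws exponential survival times with
#' pattern-specific hazards plus independent exponential censoring whose
#' rate is solved numerically to hit the target censoring fraction.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (`ExpressionMatrix`, counts), `clinical`
#'   (`ClinicalTable` with `age`, `grade`, `response` covariates), and
#'   `truth` (`SimTruth`: `pattern`, `fractions`, `planted_degs`,
#'   `linear_predictor`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  R <- as.matrix(config$reference)
  with_seed(config$seed, {
    n <- config$n_samples
    pattern <- sample.int(config$n_patterns, n, replace = TRUE)
    frac <- rdirichlet_rows(config$dirichlet_alpha[pattern, , drop = FALSE])
    colnames(frac) <- colnames(R)
    sample_ids <- sprintf("S%04d", seq_len(n))
    rownames(frac) <- sample_ids

    mix <- R %*% t(frac)                       # genes x samples expected profile
    prob <- sweep(mix, 2, colSums(mix), "/")
    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    libsize <- rlnorm_mean(n, config$library_size_mean, sdlog)
    mu <- sweep(prob, 2, libsize, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow(mu), ncol(mu), dimnames = list(rownames(R), sample_ids))

    h0 <- log(2) / config$baseline_median_days
    hazards <- h0 * config$hazard_ratios[pattern]
    cens_rate <- solve_censoring_rate(h0 * config$hazard_ratios,
                                      config$censoring_rate)
    t_event <- rexp(n, rate = hazards)
    t_cens <- rexp(n, rate = cens_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    clinical <- clinical_table(data.frame(
      sample_id = sample_ids,
      os_time = os_time,
      os_event = os_event,
      age = round(rnorm(n, 60, 10), 1),
      grade = sample.int(3, n, replace = TRUE),
      response = rbinom(n, 1, config$response_prob[pattern]),
      stringsAsFactors = FALSE))

    truth <- structure(list(
      pattern = setNames(pattern, sample_ids),
      fractions = frac,
      planted_degs = planted_deg_truth(config),
      linear_predictor = setNames(log(config$hazard_ratios)[pattern], sample_ids),
      censoring_rate_used = cens_rate),
      class = "SimTruth")

    list(expression = expression_matrix(counts, unit = "counts"),
         clinical = clinical, truth = truth)
  })
}

rlnorm_mean <- function(n, mean, sdlog) {
  exp(rnorm(n, log(mean) - sdlog^2 / 2, sdlog))
}

# Exponential event time with rate h, independent exponential censoring with
# rate c: P(censored) = c / (c + h). Solve mean over patterns = target.
solve_censoring_rate <- function(hazards, target) {
  f <- function(logc) mean(exp(logc) / (exp(logc) + hazards)) - target
  exp(uniroot(f, lower = log(min(hazards)) - 20,
              upper = log(max(hazards)) + 20)$root)
}

# Expected per-pattern expression profiles and the derived planted DEG sets
# (genes whose expected log2 fold change between two patterns exceeds 1),
# for the three pairwise contrasts and their ">= 2 of 3" intersection.
planted_deg_truth <- function(config) {
  if (config$n_patterns < 2)
    return(list(per_contrast = list(), common = character()))
  R <- as.matrix(config$reference)
  ef <- config$dirichlet_alpha / rowSums(config$dirichlet_alpha)
  mu <- R %*% t(ef)                                  # genes x patterns
  mu <- sweep(mu, 2, colSums(mu), "/")               # relative abundance
  pairs <- utils::combn(config$n_patterns, 2)
  per_contrast <- lapply(seq_len(ncol(pairs)), function(i) {
    lfc <- log2(mu[, pairs[1, i]] / mu[, pairs[2, i]])
    rownames(R)[abs(lfc) > 1]
  })
  names(per_contrast) <- apply(pairs, 2, paste, collapse = "v")
  tab <- table(unlist(per_contrast))
  list(per_contrast = per_contrast,
       common = names(tab)[tab >= 2])
}

# ---------------------------------------------------------------------------
# Mutations

# Planted 96-context signatures: column 1 is APOBEC-like (>= `tcw_mass` of
# its mass on T[C>T]W and T[C>G]W), column 2 CpG-deamination-like, column 3
# broad C>A; further columns (if requested) are sparse random profiles.
planted_mut_signatures <- function(config) {
  cats <- context_categories()
  ctx5 <- substr(cats, 1, 1); sub <- substr(cats, 3, 5); ctx3 <- substr(cats, 7, 7)
  k <- config$n_mut_signatures
  S <- matrix(0, 96, k, dimnames = list(cats, paste0("planted", seq_len(k))))
  tcw <- which(sub %in% c("C>T", "C>G") & ctx5 == "T" & ctx3 %in% c("A", "T"))
  S[tcw, 1] <- config$tcw_mass / length(tcw)
  S[-tcw, 1] <- (1 - config$tcw_mass) / (96 - length(tcw))
  if (k >= 2) {
    v <- rep(0.002, 96)
    v[sub == "C>T" & ctx3 == "G"] <- 0.23
    S[, 2] <- v / sum(v)
  }
  if (k >= 3) {
    v <- rep(0.001, 96)
    v[sub == "C>A"] <- 1 / 16
    S[, 3] <- v / sum(v)
  }
  if (k > 3) {
    with_seed(config$seed + 9601L, for (j in 4:k) {
      v <- rgamma(96, 0.2); S[, j] <- v / sum(v)
    })
  }
  S
}

category_fields <- function(cat) {
  list(f5 = substr(cat, 1, 1), ref = substr(cat, 3, 3),
       alt = substr(cat, 5, 5), f3 = substr(cat, 7, 7))
}

#' Simulate a somatic mutation table
#'
#' Per sample, draws a signature-exposure vector from a symmetric Dirichlet
#' and a multinomial mutation catalogue from the exposure-weighted planted
#' signatures, then expands each drawn context into a MAF-like record with a
#' fabricated unique position, a consistent 3-mer context and a +/-20 bp
#' window (`context41`) with uniform random flanks. Half of the records are
#' emitted on the purine strand (reverse-complemented) to exercise strand
#' collapsing. A configurable fraction of indel and Silent records is
#' appended for mutation-burden accounting.
#'
#' @param config a [sim_config()].
#' @return list with `mutations` (`MutationTable`) and `truth` (list with
#'   `signatures` 96 x k and `exposures` samples x k).
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  S <- planted_mut_signatures(config)
  cats <- rownames(S)
  chroms <- unique(toy_genome_arms()$chrom)
  with_seed(config$seed + 1L, {
    n <- config$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    expo <- rdirichlet_rows(matrix(config$exposure_alpha, n, ncol(S)))
    dimnames(expo) <- list(sample_ids, colnames(S))
    n_mut <- sample(seq(config$mutations_per_sample[1],
                        config$mutations_per_sample[2]), n, replace = TRUE)
    gene_pool <- sprintf("GENE%03d", 1:50)
    recs <- vector("list", n)
    pos_counter <- 0L
    for (s in seq_len(n)) {
      p <- as.vector(S %*% expo[s, ])
      cnt <- as.vector(rmultinom(1, n_mut[s], p))
      cat_idx <- rep.int(seq_len(96), cnt)
      m <- length(cat_idx)
      fld <- category_fields(cats[cat_idx])
      left <- random_bases(m, 19); right <- random_bases(m, 19)
      ctx3 <- paste0(fld$f5, fld$ref, fld$f3)
      ctx41 <- paste0(left, fld$f5, fld$ref, fld$f3, right)
      ref <- fld$ref; alt <- fld$alt
      flip <- runif(m) < 0.5
      if (any(flip)) {
        ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
        alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
        ctx3[flip] <- revcomp(ctx3[flip])
        ctx41[flip] <- revcomp(ctx41[flip])
      }
      n_sil <- round(config$silent_fraction * m)
      vclass <- rep("Missense_Mutation", m)
      if (n_sil > 0) vclass[sample.int(m, n_sil)] <- "Silent"
      n_ind <- round(config$indel_fraction * m)
      pos <- pos_counter + seq_len(m + n_ind)
      pos_counter <- pos_counter + m + n_ind
      rec <- data.frame(
        sample_id = sample_ids[s],
        chrom = sample(chroms, m + n_ind, replace = TRUE),
        pos = pos,
        ref = c(ref, rep("A", n_ind)),
        alt = c(alt, rep("-", n_ind)),
        variant_class = c(vclass,
                          sample(c("Frame_Shift_Del", "Frame_Shift_Ins",
                                   "In_Frame_Del"), n_ind, replace = TRUE)),
        context = c(ctx3, rep(NA, n_ind)),
        context41 = c(ctx41, rep(NA, n_ind)),
        gene = sample(gene_pool, m + n_ind, replace = TRUE),
        stringsAsFactors = FALSE)
      recs[[s]] <- rec
    }
    muts <- mutation_table(do.call(rbind, recs), contigs = chroms)
    list(mutations = muts, truth = list(signatures = S, exposures = expo))
  })
}

random_bases <- function(n, len) {
  m <- matrix(sample(BASES, n * len, replace = TRUE), n, len)
  apply(m, 1, paste, collapse = "")
}

# ---------------------------------------------------------------------------
# Copy number

#' Simulate a copy-number segment table
#'
#' Background segment values are Normal(0, `background_sd`) on random
#' breakpoints over the toy genome; each planted arm event adds its effect
#' to a whole arm in the stated fraction of samples, and each planted focal
#' peak adds its effect to its window in the stated fraction.
#'
#' @param config a [sim_config()].
#' @return list with `segments` (`SegmentTable`) and `truth` (per-sample
#'   logical matrices `arm_events`, `focal_events`).
#' @export
simulate_cnv <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  arms <- toy_genome_arms()
  chroms <- unique(arms$chrom)
  chrom_len <- setNames(vapply(chroms, function(ch)
    max(arms$end[arms$chrom == ch]), 0), chroms)
  arm_ev <- config$planted_arm_events
  foc_ev <- config$planted_focal_peaks
  with_seed(config$seed + 2L, {
    n <- config$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    # plant each event in an exact fraction of samples (random identity)
    plant <- function(fracs) {
      m <- matrix(FALSE, n, length(fracs))
      for (j in seq_along(fracs)) m[sample.int(n, round(fracs[j] * n)), j] <- TRUE
      m
    }
    has_arm <- plant(arm_ev$fraction)
    dimnames(has_arm) <- list(sample_ids, arm_ev$arm)
    has_foc <- plant(foc_ev$fraction)
    foc_names <- if (nrow(foc_ev)) paste0(foc_ev$chrom, ":", foc_ev$start) else character(0)
    dimnames(has_foc) <- list(sample_ids, foc_names)
    segs <- vector("list", n * length(chroms))
    si <- 0L
    for (s in seq_len(n)) {
      for (ch in chroms) {
        len <- chrom_len[[ch]]
        cuts <- sort(sample.int(len - 1, 3))
        bounds <- c(0, cuts)
        ai <- which(arm_ev$arm %in% arms$arm[arms$chrom == ch] & has_arm[s, ])
        for (a in ai) {
          adef <- arms[arms$arm == arm_ev$arm[a], ]
          bounds <- c(bounds, adef$start - 1, adef$end)
        }
        fi <- which(foc_ev$chrom == ch & has_foc[s, ])
        for (f in fi) bounds <- c(bounds, foc_ev$start[f] - 1, foc_ev$end[f])
        bounds <- sort(unique(pmin(pmax(bounds, 0), len)))
        if (bounds[length(bounds)] < len) bounds <- c(bounds, len)
        start <- bounds[-length(bounds)] + 1
        end <- bounds[-1]
        val <- rnorm(length(start), 0, config$background_sd)
        for (a in ai) {
          adef <- arms[arms$arm == arm_ev$arm[a], ]
          hit <- start >= adef$start & end <= adef$end
          val[hit] <- val[hit] + arm_ev$effect[a]
        }
        for (f in fi) {
          hit <- start >= foc_ev$start[f] & end <= foc_ev$end[f]
          val[hit] <- val[hit] + foc_ev$effect[f]
        }
        si <- si + 1L
        segs[[si]] <- data.frame(sample_id = sample_ids[s], chrom = ch,
                                 start = start, end = end, value = val,
                                 stringsAsFactors = FALSE)
      }
    }
    list(segments = segment_table(do.call(rbind, segs[seq_len(si)])),
         truth = list(arm_events = has_arm, focal_events = has_foc))
  })
}
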