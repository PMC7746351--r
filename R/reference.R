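# Bundled synthetic reference objects. All are generated deterministically in
# code (no external data): a block-structured 22-cell-type signature matrix,
# a synthetic 30-column COSMIC-v2-like mutational-signature reference, and a
# toy genome arm table for copy-number analyses.

LM22_CELL_TYPES <- c(
  "B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
  "T cells CD4 naive", "T cells CD4 memory resting",
  "T cells CD4 memory activated", "T cells follicular helper",
  "T cells regulatory (Tregs)", "T cells gamma delta", "NK cells resting",
  "NK cells activated", "Monocytes", "Macrophages M0", "Macrophages M1",
  "Macrophages M2", "Dendritic cells resting", "Dendritic cells activated",
  "Mast cells resting", "Mast cells activated", "Eosinophils", "Neutrophils")

#' Bundled synthetic cell-type signature matrix
#'
#' A deterministic, synthetic 500-gene x 22-cell-type reference in the style
#' of the LM22 leukocyte matrix: each cell type carries a block of 20 marker
#' genes expressed around 30-fold above their level in other types, plus 60
#' shared moderately expressed genes. It is a stand-in generated by this
#' package, not the real LM22 file; a real signature matrix can be supplied
#' to any function that accepts a `SignatureMatrixRef`.
#'
#' @param markers_per_type marker genes per cell type (default 20).
#' @param n_shared shared non-marker genes (default 60).
#' @return A `SignatureMatrixRef` (genes x 22).
#' @export
synthetic_lm22 <- function(markers_per_type = 20, n_shared = 60) {
  n_types <- length(LM22_CELL_TYPES)
  with_seed(772200L, {
    n_marker <- markers_per_type * n_types
    genes <- sprintf("SYN%04d", seq_len(n_marker + n_shared))
    m <- matrix(runif(n_marker * n_types, 5, 30), n_marker, n_types)
    for (k in seq_len(n_types)) {
      rows <- (k - 1) * markers_per_type + seq_len(markers_per_type)
      m[rows, k] <- runif(markers_per_type, 300, 600)
    }
    shared <- matrix(rep(runif(n_shared, 50, 150), n_types), n_shared, n_types)
    shared <- shared * matrix(runif(n_shared * n_types, 0.9, 1.1), n_shared, n_types)
    m <- rbind(m, shared)
    dimnames(m) <- list(genes, LM22_CELL_TYPES)
    signature_matrix_ref(m)
  })
}

# 96 trinucleotide substitution categories: 6 pyrimidine substitutions x
# 4 five-prime x 4 three-prime bases, lexicographic within substitution.
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide substitution categories
#'
#' Category order: the six pyrimidine substitutions (C>A, C>G, C>T, T>A,
#' T>C, T>G), each expanded over the 4 x 4 flanking bases in lexicographic
#' order, written as e.g. `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
context_categories <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s) {
    as.vector(t(outer(BASES, BASES, function(f, t3)
      paste0(f, "[", s, "]", t3))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""), ""))
}

#' Bundled synthetic COSMIC-v2-like signature reference
#'
#' A deterministic synthetic stand-in for the 30-signature COSMIC v2
#' reference: 96-category probability profiles whose first columns mimic the
#' qualitative shapes of well-known processes (spontaneous CpG deamination,
#' APOBEC C>T/C>G at TpCpW, tobacco C>A, UV C>T at dipyrimidines, mismatch-
#' repair deficiency), the remainder being random sparse profiles. Column
#' names are `Signature.1` ... `Signature.30`. It is synthetic: cosine
#' matches against it identify shapes, not aetiologies; a real reference can
#' be loaded with [read_signature_matrix()] and passed wherever a signature
#' reference is accepted.
#'
#' @return A 96 x 30 matrix, columns summing to 1.
#' @export
synthetic_cosmic_reference <- function() {
  cats <- context_categories()
  with_seed(300096L, {
    m <- matrix(0, 96, 30, dimnames = list(cats, sprintf("Signature.%d", 1:30)))
    peak <- function(idx, jitter = TRUE) {
      v <- rep(0.001, 96)
      v[idx] <- if (jitter) runif(length(idx), 0.5, 1.5) else 1
      v / sum(v)
    }
    ctx5 <- substr(cats, 1, 1); sub <- substr(cats, 3, 5); ctx3 <- substr(cats, 7, 7)
    # 1: C>T at NpCpG (CpG deamination-like)
    m[, 1] <- peak(which(sub == "C>T" & ctx3 == "G"))
    # 2: C>T at TpCpW (APOBEC-like)
    m[, 2] <- peak(which(sub == "C>T" & ctx5 == "T" & ctx3 %in% c("A", "T")), jitter = FALSE)
    # 4: C>A broad (tobacco-like)
    m[, 4] <- peak(which(sub == "C>A"))
    # 6: C>T at GpCpN (mismatch-repair-deficiency-like)
    m[, 6] <- peak(which(sub == "C>T" & ctx5 == "G"))
    # 7: C>T at dipyrimidine sites (UV-like): 5' C or T
    m[, 7] <- peak(which(sub == "C>T" & ctx5 %in% c("C", "T")))
    # 13: C>G at TpCpW (APOBEC-like)
    m[, 13] <- peak(which(sub == "C>G" & ctx5 == "T" & ctx3 %in% c("A", "T")), jitter = FALSE)
    rest <- setdiff(1:30, c(1, 2, 4, 6, 7, 13))
    for (k in rest) {
      v <- rgamma(96, shape = 0.15)
      m[, k] <- v / sum(v)
    }
    m
  })
}

#' Toy genome arm table
#'
#' Four 100-Mb chromosomes, each split at 50 Mb into p and q arms; used by
#' the synthetic copy-number generator and as the default arm definition for
#' arm-level scoring on synthetic cohorts.
#'
#' @return data.frame with `chrom`, `arm`, `start`, `end` (1-based inclusive).
#' @export
toy_genome_arms <- function() {
  chroms <- paste0("chr", 1:4)
  data.frame(
    chrom = rep(chroms, each = 2),
    arm = paste0(rep(chroms, each = 2), rep(c("p", "q"), 4)),
    start = rep(c(1, 5e7 + 1), 4),
    end = rep(c(5e7, 1e8), 4),
    stringsAsFactors = FALSE)
}
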