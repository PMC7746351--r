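#' Construct an expression matrix
#'
#' A thin container around a numeric genes x samples matrix carrying a unit
#' tag. Counts must be non-negative; all values must be finite; gene and
#' sample identifiers must be unique. Gene identifiers are upper-cased and
#' whitespace-stripped so that matching against signature matrices and gene
#' sets is an exact string comparison.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param unit one of `"counts"`, `"logcpm"`, `"normalized"`.
#' @return An object of class `ExpressionMatrix`: the matrix with a `unit`
#'   attribute.
#' @export
expression_matrix <- function(values, unit = c("counts", "logcpm", "normalized")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  rownames(values) <- normalize_gene_ids(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (unit == "counts" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  structure(values, unit = unit, class = c("ExpressionMatrix", "matrix", "array"))
}

normalize_gene_ids <- function(x) toupper(trimws(as.character(x)))

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [unit: %s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return `"counts"`, `"logcpm"` or `"normalized"`.
#' @export
expression_unit <- function(x) attr(x, "unit")

#' Read a genes x samples expression table
#'
#' Expects a TSV whose first column holds gene identifiers and whose header
#' row holds sample identifiers. Duplicate gene rows are collapsed by keeping
#' the row with the largest mean expression (logged). Duplicate sample ids
#' are fatal.
#'
#' @param path TSV file path.
#' @param unit unit tag to attach (`counts`, `logcpm`, `normalized`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, unit = "counts") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample column")
  genes <- normalize_gene_ids(df[[1]])
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                 bad[1], genes[bad[1]], samples[bad[2]]))
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    tme_log("collapsing %d duplicated gene id(s) by max mean expression: %s",
            length(dup), paste(head(dup, 5), collapse = ", "))
    ord <- order(-rowMeans(num))   # keep highest-mean profile per gene
    num <- num[ord, , drop = FALSE]
    num <- num[!duplicated(rownames(num)), , drop = FALSE]
    num <- num[match(unique(genes), rownames(num)), , drop = FALSE]
  }
  expression_matrix(num, unit = unit)
}

#' Write an expression matrix as TSV
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @param id_column header name for the gene-id column.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), as.matrix(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time` (days, non-negative) and
#' `os_event` (0/1). Any further columns are kept as covariates.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Validate a clinical data.frame
#' @param df data.frame with `sample_id`, `os_time`, `os_event` plus optional
#'   covariate columns.
#' @return the validated data.frame, classed `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop("os_time must be finite and >= 0")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0/1")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' The nine recognised somatic variant classifications
#'
#' Records with any other classification are remapped to `"other"` on read
#' (with a logged count); `Silent` is kept as-is but excluded from
#' non-silent mutation-burden counting.
#' @export
VARIANT_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
                     "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins",
                     "In_Frame_Del", "Splice_Site", "Translation_Start_Site")

#' Read a MAF-like somatic mutation table
#'
#' Mandatory columns: `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`.
#' Optional: `CONTEXT` (3-mer with the mutated base centred, reference
#' strand), `CONTEXT41` (+/-20 bp window), `Hugo_Symbol`. Records whose
#' classification is not one of the nine recognised classes are remapped to
#' `"other"` and counted in the log.
#'
#' @param path TSV file path.
#' @param contigs optional declared contig set; chromosomes outside it are fatal.
#' @return A `data.frame` of class `MutationTable` with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_class`, and when available
#'   `context`, `context41`, `gene`.
#' @export
read_maf <- function(path, contigs = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
            "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("MAF missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
                    chrom = as.character(df$Chromosome),
                    pos = as.integer(df$Start_Position),
                    ref = toupper(as.character(df$Reference_Allele)),
                    alt = toupper(as.character(df$Tumor_Seq_Allele2)),
                    variant_class = as.character(df$Variant_Classification),
                    stringsAsFactors = FALSE)
  if ("CONTEXT" %in% colnames(df)) out$context <- toupper(as.character(df$CONTEXT))
  if ("CONTEXT41" %in% colnames(df)) out$context41 <- toupper(as.character(df$CONTEXT41))
  if ("Hugo_Symbol" %in% colnames(df)) out$gene <- normalize_gene_ids(df$Hugo_Symbol)
  mutation_table(out, contigs = contigs)
}

#' Validate a mutation data.frame
#' @param df data.frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class` and optional `context`, `context41`, `gene` columns.
#' @param contigs optional declared contig set.
#' @return the validated data.frame, classed `MutationTable`.
#' @export
mutation_table <- function(df, contigs = NULL) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  unknown <- !(df$variant_class %in% c(VARIANT_CLASSES, "Silent", "other"))
  if (any(unknown)) {
    tme_log("remapping %d record(s) with unknown variant class to 'other'", sum(unknown))
    df$variant_class[unknown] <- "other"
  }
  if (!is.null(contigs) && !all(df$chrom %in% contigs))
    stop("chromosome(s) outside declared contig set: ",
         paste(unique(setdiff(df$chrom, contigs)), collapse = ", "))
  snv <- is_snv(df)
  if (any(snv & df$ref == df$alt))
    stop("SNV record(s) with ref == alt at row(s): ",
         paste(head(which(snv & df$ref == df$alt), 5), collapse = ", "))
  if ("context" %in% colnames(df)) {
    bad <- snv & !is.na(df$context) & nchar(df$context) == 3 &
      substr(df$context, 2, 2) != df$ref
    if (any(bad))
      stop("context middle base != ref for SNV record(s) at row(s): ",
           paste(head(which(bad), 5), collapse = ", "))
  }
  class(df) <- c("MutationTable", "data.frame")
  df
}

is_snv <- function(df) {
  nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
}

#' Read a SEG-like copy-number segment table
#'
#' Mandatory columns: `Sample`, `Chromosome`, `Start`, `End`, `value`
#' (1-based inclusive coordinates, caller-relative copy-number measure).
#' Segments of one sample on one chromosome must not overlap.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `SegmentTable` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `value`.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "value")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("SEG missing column(s): ", paste(miss, collapse = ", "))
  segment_table(data.frame(sample_id = as.character(df$Sample),
                           chrom = as.character(df$Chromosome),
                           start = as.numeric(df$Start),
                           end = as.numeric(df$End),
                           value = as.numeric(df$value),
                           stringsAsFactors = FALSE))
}

#' Validate a segment data.frame
#' @param df data.frame with `sample_id`, `chrom`, `start`, `end`, `value`.
#' @return the validated data.frame, classed `SegmentTable`.
#' @export
segment_table <- function(df) {
  need <- c("sample_id", "chrom", "start", "end", "value")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("segment table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("segment start > end at record(s): ", paste(head(bad, 5), collapse = ", "))
  # non-overlap within sample x chrom (1-based inclusive)
  key <- split(seq_len(nrow(df)), paste(df$sample_id, df$chrom, sep = "\r"))
  for (idx in key) {
    if (length(idx) < 2) next
    o <- idx[order(df$start[idx])]
    if (any(df$start[o][-1] <= df$end[o][-length(o)]))
      stop("overlapping segments for sample '", df$sample_id[o[1]],
           "' on chromosome '", df$chrom[o[1]], "'")
  }
  class(df) <- c("SegmentTable", "data.frame")
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Set names must be unique and sets non-empty.
#'
#' @param path GMT file path.
#' @return A list of class `GeneSetCollection`: `sets` (named list of gene
#'   vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: ", paste(head(short, 5), collapse = ", "))
  names <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names))
    stop("duplicate gene-set name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(normalize_gene_ids(p[-(1:2)])))
  names(sets) <- names
  descriptions <- setNames(vapply(parts, `[[`, "", 2L), names)
  gene_set_collection(sets, descriptions)
}

#' Construct a gene-set collection
#' @param sets named list of gene-id character vectors.
#' @param descriptions optional named character vector of descriptions.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (any(!vapply(sets, length, 1L)))
    stop("empty gene set(s): ",
         paste(names(sets)[!vapply(sets, length, 1L)], collapse = ", "))
  sets <- lapply(sets, normalize_gene_ids)
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' Write a gene-set collection as GMT
#' @param gsc a `GeneSetCollection`.
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-type reference signature matrix
#'
#' TSV with gene ids in the first column and cell-type names in the header.
#' Requires at least two cell types, unique genes, finite values.
#'
#' @param path TSV file path.
#' @return A numeric genes x cell-types matrix of class `SignatureMatrixRef`.
#' @export
read_signature_matrix <- function(path) {
  x <- read_expression(path, unit = "normalized")
  signature_matrix_ref(as.matrix(x))
}

#' Validate a signature reference matrix
#' @param m numeric genes x cell-types matrix with dimnames.
#' @return the matrix, classed `SignatureMatrixRef`.
#' @export
signature_matrix_ref <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("reference must be a numeric matrix")
  if (ncol(m) < 2) stop("reference needs >= 2 cell types")
  rownames(m) <- normalize_gene_ids(rownames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate genes in reference")
  if (any(!is.finite(m))) stop("non-finite value in reference")
  structure(m, class = c("SignatureMatrixRef", "matrix", "array"))
}

#' Write a generic data.frame result as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
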