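#' Export a call set as VCF plus annotation and sample tables
#'
#' Writes the genotypes as a minimal multi-sample VCF v4.2 (GT field, 1-based
#' positions, missing calls as "./."), the variant annotations as a TSV, and
#' the sample sheet as a TSV. The three files round-trip through
#' [read_cohort()].
#'
#' @param cs a [callset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cs, dir, prefix = "cohort") {
  stopifnot(inherits(cs, "callset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             annotations = file.path(dir, paste0(prefix, ".annotations.tsv")),
             samples = file.path(dir, paste0(prefix, ".samples.tsv")))

  v <- cs$variants
  con <- file(paths[["vcf"]], "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", cs$samples$sample_id),
                     collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  G <- methods::as(cs$geno, "TsparseMatrix")
  M <- methods::as(cs$missing, "TsparseMatrix")
  g_by_var <- split(seq_along(G@j), G@j)
  m_by_var <- split(seq_along(M@j), M@j)
  for (j in seq_len(nrow(v))) {
    row <- rep.int("0/0", nrow(cs$samples))
    gi <- g_by_var[[as.character(j - 1L)]]
    if (length(gi)) row[G@i[gi] + 1L] <- gt_str[G@x[gi] + 1L]
    mi <- m_by_var[[as.character(j - 1L)]]
    if (length(mi)) row[M@i[mi] + 1L] <- "./."
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT", row),
                     collapse = "\t"), con)
  }
  utils::write.table(v, paths[["annotations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cs$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Assemble a call set from VCF, annotation TSV and sample TSV
#'
#' Inverse of [write_cohort()]: parses the multi-sample VCF (via vcfR),
#' joins the annotation table on variant ID, and rebuilds the sparse
#' genotype and missingness matrices. An optional coverage TSV
#' (`variant_id`, `sample_id` of uncovered cells) populates the coverage
#' indicators; by default all sites are treated as covered.
#'
#' @param vcf,annotations,samples file paths.
#' @param uncovered optional path to a TSV of uncovered (variant, sample)
#'   pairs.
#' @return A [callset()].
#' @export
read_cohort <- function(vcf, annotations, samples, uncovered = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the vcfR package")
  smp <- utils::read.delim(samples, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  if (!identical(sort(ids), sort(ann$variant_id)))
    stop("annotation table and VCF disagree on variant IDs")
  ann <- ann[match(ids, ann$variant_id), , drop = FALSE]
  gt <- gt[, match(smp$sample_id, colnames(gt)), drop = FALSE]

  alt_count <- matrix(0L, nrow(gt), ncol(gt))
  alt_count[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  alt_count[gt %in% c("1/1", "1|1")] <- 2L
  mis <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  geno <- methods::as(methods::as(Matrix::Matrix(t(alt_count), sparse = TRUE),
                                  "CsparseMatrix"), "generalMatrix")
  missing <- if (any(mis)) methods::as(Matrix::Matrix(t(mis), sparse = TRUE),
                                       "nsparseMatrix") else NULL
  unc <- NULL
  if (!is.null(uncovered)) {
    u <- utils::read.delim(uncovered, stringsAsFactors = FALSE)
    unc <- Matrix::sparseMatrix(
      i = match(u$sample_id, smp$sample_id),
      j = match(u$variant_id, ann$variant_id),
      dims = c(nrow(smp), nrow(ann)))
  }
  callset(smp, ann, geno, missing = missing, uncovered = unc)
}

#' Write a burden-result table as TSV
#'
#' Columns mirror the published result layout: model, gene, carrier counts
#' and totals, carrier frequencies, p-value, odds ratio and threshold flags.
#'
#' @param result a `burden_result` from [collapse_and_test()].
#' @param path output file.
#' @export
write_burden_tsv <- function(result, path) {
  stopifnot(inherits(result, "burden_result"))
  cols <- c("model", "gene", "case_carriers", "cases_total",
            "control_carriers", "controls_total", "case_freq",
            "control_freq", "p_value", "odds_ratio",
            "genome_wide", "study_wide")
  utils::write.table(result[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
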