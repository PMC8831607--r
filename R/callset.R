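#' @importFrom Matrix sparseMatrix colSums rowSums t
NULL

#' Variant effect classes
#'
#' Effect classes recognized by the qualifying-variant models. `lof_effects()`
#' returns the subset treated as loss-of-function (protein-truncating or
#' canonical-splice-disrupting) classes.
#'
#' @return Character vector of effect class names.
#' @export
effect_classes <- function() {
  c("stop_gained", "frameshift", "splice_acceptor", "splice_donor",
    "start_lost", "stop_lost", "missense", "synonymous", "splice_region")
}

#' @rdname effect_classes
#' @export
lof_effects <- function() {
  c("stop_gained", "frameshift", "splice_acceptor", "splice_donor",
    "start_lost", "stop_lost")
}

#' Construct a case/control call set
#'
#' A `callset` bundles the sample sheet, the per-variant annotation table, the
#' genotype matrix and the per-site coverage indicators of a sequenced cohort.
#' Genotypes are stored sparsely (rare variants make the matrix overwhelmingly
#' reference): `geno` holds 0 = hom-ref, 1 = het, 2 = hom-alt; `missing` and
#' `uncovered` are sparse pattern matrices flagging no-calls and samples with
#' depth below the coverage cutoff (10x proxy) at a site.
#'
#' Two structural invariants are enforced: a non-reference genotype implies the
#' site is covered for that sample, and a genotype flagged missing is stored
#' as 0 in `geno`.
#'
#' @param samples data.frame with columns `sample_id` (unique) and `status`
#'   ("case" or "control").
#' @param variants data.frame of variant annotations. Must contain
#'   `variant_id` (unique), `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`;
#'   qualifying models additionally read `gnomad_af_*` columns, `case_af`,
#'   `control_af`, `polyphen_humvar`, `trap_score` and `qc_pass`.
#' @param geno sparse or dense numeric matrix, samples x variants, values in
#'   \{0, 1, 2\}.
#' @param missing,uncovered optional sparse pattern matrices (same shape as
#'   `geno`); `NULL` means no missing calls / full coverage.
#' @param meta optional list of provenance metadata (e.g. the simulation seed).
#'
#' @return An object of class `callset`.
#' @export
callset <- function(samples, variants, geno, missing = NULL, uncovered = NULL,
                    meta = list()) {
  stopifnot(is.data.frame(samples), is.data.frame(variants))
  if (!all(c("sample_id", "status") %in% names(samples)))
    stop("`samples` needs columns sample_id and status")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs")
  if (!all(samples$status %in% c("case", "control")))
    stop("sample status must be 'case' or 'control'")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant IDs")
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "gene", "effect")
  miss_cols <- setdiff(need, names(variants))
  if (length(miss_cols))
    stop("`variants` missing columns: ", paste(miss_cols, collapse = ", "))
  if (!all(variants$effect %in% effect_classes()))
    stop("unknown effect class in annotations")

  geno <- methods::as(methods::as(geno, "CsparseMatrix"), "generalMatrix")
  ns <- nrow(samples); nv <- nrow(variants)
  if (!identical(dim(geno), c(ns, nv)))
    stop("geno dimensions do not match sample/variant tables")
  if (length(geno@x) && !all(geno@x %in% c(0, 1, 2)))
    stop("genotype codes must be 0, 1 or 2")
  dimnames(geno) <- list(samples$sample_id, variants$variant_id)

  pat <- function(m) {
    if (is.null(m))
      return(sparseMatrix(i = integer(), j = integer(), dims = c(ns, nv),
                          dimnames = dimnames(geno)))
    m <- methods::as(m, "nsparseMatrix")
    if (!identical(dim(m), c(ns, nv))) stop("mask dimensions mismatch")
    dimnames(m) <- dimnames(geno)
    m
  }
  missing <- pat(missing); uncovered <- pat(uncovered)

  # non-ref genotype at an uncovered or missing cell violates the contract
  bad <- geno * (uncovered + missing)
  if (length(bad@x) && any(bad@x != 0))
    stop("non-reference genotype at an uncovered or missing cell")

  structure(
    list(samples = samples, variants = variants, geno = geno,
         missing = missing, uncovered = uncovered, meta = meta),
    class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %d samples (%d cases / %d controls), %d variants, %d genes\n",
              nrow(x$samples), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"),
              nrow(x$variants), length(unique(x$variants$gene))))
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' @export
dim.callset <- function(x) c(nrow(x$samples), nrow(x$variants))

case_idx <- function(cs) which(cs$samples$status == "case")
control_idx <- function(cs) which(cs$samples$status == "control")

#' Cohort sizes of a call set
#' @param cs a [callset()].
#' @return Named integer vector with elements `cases` and `controls`.
#' @export
cohort_sizes <- function(cs) {
  c(cases = sum(cs$samples$status == "case"),
    controls = sum(cs$samples$status == "control"))
}

#' Per-site covered-sample counts by cohort
#'
#' Counts, for every variant site, how many case and control samples are
#' covered (depth >= 10 proxy) — the input of the coverage-harmonization test.
#'
#' @param cs a [callset()].
#' @return data.frame with `variant_id`, `covered_cases`, `covered_controls`.
#' @export
covered_counts <- function(cs) {
  ci <- case_idx(cs); ki <- control_idx(cs)
  data.frame(
    variant_id = cs$variants$variant_id,
    covered_cases = length(ci) - colSums(cs$uncovered[ci, , drop = FALSE]),
    covered_controls = length(ki) - colSums(cs$uncovered[ki, , drop = FALSE]),
    row.names = NULL)
}

#' Drop variants from a call set
#' @param cs a [callset()].
#' @param variant_ids IDs of variants to remove.
#' @return The reduced `callset`.
#' @export
drop_variants <- function(cs, variant_ids) {
  keep <- !(cs$variants$variant_id %in% variant_ids)
  callset(cs$samples, cs$variants[keep, , drop = FALSE],
          cs$geno[, keep, drop = FALSE],
          cs$missing[, keep, drop = FALSE],
          cs$uncovered[, keep, drop = FALSE], cs$meta)
}

#' Recompute internal case/control allele frequencies from genotypes
#'
#' Allele frequencies are alternate-allele counts over called alleles
#' (missing and uncovered genotypes excluded from the denominator).
#'
#' @param cs a [callset()].
#' @return `cs` with `case_af` and `control_af` columns refreshed.
#' @export
update_internal_af <- function(cs) {
  af_for <- function(idx) {
    n_called <- length(idx) -
      colSums(cs$missing[idx, , drop = FALSE]) -
      colSums(cs$uncovered[idx, , drop = FALSE])
    ac <- colSums(cs$geno[idx, , drop = FALSE])
    ifelse(n_called > 0, ac / (2 * n_called), 0)
  }
  cs$variants$case_af <- as.numeric(af_for(case_idx(cs)))
  cs$variants$control_af <- as.numeric(af_for(control_idx(cs)))
  cs
}
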