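#' Phased haplotype matrix
#'
#' Container for pre-phased haplotypes over a gene region (phasing itself,
#' e.g. by SHAPEIT, is upstream of this package). Each sample contributes two
#' haplotype rows; alleles are coded 0 (ref), 1 (alt), NA (missing).
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param haps integer matrix of alleles, `2 * n_samples` rows (sample order,
#'   haplotype 1 then 2 interleaved) by `n_variants` columns.
#' @param sample_ids character vector of sample IDs.
#' @return An object of class `phased_matrix`.
#' @export
phased_matrix <- function(variants, haps, sample_ids) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "chrom", "pos", "ref", "alt") %in%
                  names(variants)))
  haps <- as.matrix(haps)
  if (nrow(haps) != 2 * length(sample_ids))
    stop("need exactly two haplotypes per sample")
  if (ncol(haps) != nrow(variants))
    stop("haplotype/variant dimension mismatch")
  if (!all(haps %in% c(0L, 1L, NA)))
    stop("allele codes must be 0, 1 or NA")
  rownames(haps) <- paste0(rep(sample_ids, each = 2), "|", c(1, 2))
  colnames(haps) <- variants$variant_id
  structure(list(variants = variants, haps = haps, sample_ids = sample_ids),
            class = "phased_matrix")
}

#' @export
print.phased_matrix <- function(x, ...) {
  cat(sprintf("<phased_matrix> %d samples (%d haplotypes) x %d variants\n",
              length(x$sample_ids), nrow(x$haps), ncol(x$haps)))
  invisible(x)
}

#' Read phased haplotypes from a VCF
#'
#' Reads a phased multi-sample VCF (GT fields "a|b") into a
#' [phased_matrix()]. Unphased genotypes raise an error; multiallelic sites
#' are kept (alleles > 1 treated as alt) and can be removed with
#' [filter_phasing_input()].
#'
#' @param path VCF file path.
#' @return A `phased_matrix`.
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                        fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  smp <- colnames(gt)
  known <- !is.na(gt)
  if (any(grepl("/", gt[known], fixed = TRUE)))
    stop("unphased genotypes present; phase upstream first")
  code <- function(tok) {
    out <- suppressWarnings(as.integer(tok))
    ifelse(is.na(out), NA_integer_, pmin(out, 1L))
  }
  sp <- strsplit(ifelse(is.na(gt), ".|.", gt), "|", fixed = TRUE)
  a1 <- vapply(sp, function(z) z[1], "")
  a2 <- vapply(sp, function(z) if (length(z) > 1) z[2] else ".", "")
  # gt is variants x samples; split each sample into its two haplotype rows
  A1 <- matrix(code(a1), nrow(gt), ncol(gt))
  A2 <- matrix(code(a2), nrow(gt), ncol(gt))
  haps <- matrix(NA_integer_, 2 * length(smp), nrow(variants))
  for (s in seq_along(smp)) {
    haps[2 * s - 1, ] <- A1[, s]
    haps[2 * s, ] <- A2[, s]
  }
  phased_matrix(variants, haps, smp)
}

#' Filter a region's sites for haplotype construction
#'
#' Removes multiallelic sites and sites with genotype data missing in more
#' than `max_missing` of samples (a site missing in exactly the threshold
#' fraction is retained), the pre-phasing site filters used before manual
#' haplotype assignment.
#'
#' @param pm a [phased_matrix()].
#' @param max_missing maximum tolerated per-site missing-sample fraction
#'   (default 0.20).
#' @return list with `pm` (filtered matrix), `removed` (data.frame
#'   `variant_id`, `rule`), and per-rule counts `n_multiallelic`,
#'   `n_high_missing`.
#' @export
filter_phasing_input <- function(pm, max_missing = 0.20) {
  stopifnot(inherits(pm, "phased_matrix"))
  if (!ncol(pm$haps)) stop("empty region")
  multi <- grepl(",", pm$variants$alt, fixed = TRUE)
  ns <- length(pm$sample_ids)
  sample_missing <- (is.na(pm$haps[seq(1, 2 * ns, 2), , drop = FALSE]) |
                       is.na(pm$haps[seq(2, 2 * ns, 2), , drop = FALSE]))
  miss_rate <- colSums(sample_missing) / ns
  high_miss <- !multi & miss_rate > max_missing
  drop <- multi | high_miss
  removed <- data.frame(
    variant_id = pm$variants$variant_id[drop],
    rule = ifelse(multi[drop], "multiallelic", "missingness"),
    row.names = NULL)
  keep <- !drop
  out <- phased_matrix(pm$variants[keep, , drop = FALSE],
                       pm$haps[, keep, drop = FALSE], pm$sample_ids)
  list(pm = out, removed = removed,
       n_multiallelic = sum(multi), n_high_missing = sum(high_miss))
}

#' Count distinct haplotype backgrounds carrying a focal allele
#'
#' Groups the haplotypes carrying the focal alternate allele by exact
#' identity over the non-missing flanking sites. Many distinct backgrounds
#' indicate a recurrent (hotspot) mutation; a single shared background
#' indicates a founder allele. Carrier haplotypes whose missing data leave
#' them identity-compatible with two or more established groups are counted
#' inconclusive rather than assigned; a haplotype compatible with exactly one
#' group joins it, and one compatible with none founds a new group.
#' Completely typed haplotypes are grouped first, then incomplete ones in a
#' deterministic order (fewest missing sites first, then allele pattern), so
#' the result is invariant to sample order.
#'
#' @param pm a [phased_matrix()].
#' @param focal variant ID of the focal allele (or "chrom:pos:ref:alt").
#' @param informative_only restrict the flanking comparison to sites carrying
#'   the alternate allele on at least one haplotype in the region (the
#'   informative-site restriction used in manual assignment); default TRUE.
#' @return list with `n_haplotypes` (distinct carrier backgrounds),
#'   `n_assigned`, `n_inconclusive`, and `assignments` (data.frame `hap`,
#'   `sample_id`, `group`; group NA = inconclusive).
#' @export
count_carrier_haplotypes <- function(pm, focal, informative_only = TRUE) {
  stopifnot(inherits(pm, "phased_matrix"))
  fi <- match(focal, pm$variants$variant_id)
  if (is.na(fi))
    fi <- match(focal, with(pm$variants, paste(chrom, pos, ref, alt,
                                               sep = ":")))
  if (is.na(fi)) stop("focal variant not found")
  carrier <- which(!is.na(pm$haps[, fi]) & pm$haps[, fi] == 1L)
  if (!length(carrier)) {
    warning("focal allele carried by no haplotype")
    return(list(n_haplotypes = 0L, n_assigned = 0L, n_inconclusive = 0L,
                assignments = data.frame(hap = character(),
                                         sample_id = character(),
                                         group = integer())))
  }
  flank <- setdiff(seq_len(ncol(pm$haps)), fi)
  if (informative_only) {
    has_alt <- colSums(pm$haps == 1L, na.rm = TRUE) > 0
    flank <- setdiff(which(has_alt), fi)
  }
  H <- pm$haps[carrier, flank, drop = FALSE]

  nmiss <- rowSums(is.na(H))
  pat <- apply(H, 1, function(z)
    paste(ifelse(is.na(z), ".", z), collapse = ""))
  ord <- order(nmiss, pat)
  groups <- list()           # each: representative consensus pattern (vector)
  assign <- rep(NA_integer_, length(carrier))
  compatible <- function(x, y) {
    both <- !is.na(x) & !is.na(y)
    all(x[both] == y[both])
  }
  for (r in ord) {
    z <- H[r, ]
    comp <- which(vapply(groups, compatible, TRUE, x = z))
    if (length(comp) == 1) {
      assign[r] <- comp
      g <- groups[[comp]]
      fill <- is.na(g) & !is.na(z)
      g[fill] <- z[fill]     # refine group consensus with new information
      groups[[comp]] <- g
    } else if (length(comp) == 0) {
      groups[[length(groups) + 1]] <- z
      assign[r] <- length(groups)
    }                         # >= 2 compatible groups: inconclusive
  }
  hap_names <- rownames(pm$haps)[carrier]
  list(n_haplotypes = length(groups),
       n_assigned = sum(!is.na(assign)),
       n_inconclusive = sum(is.na(assign)),
       assignments = data.frame(
         hap = hap_names,
         sample_id = sub("\\|[12]$", "", hap_names),
         group = assign, row.names = NULL))
}

#' Classify a variant as a CpG-deamination transition
#'
#' Spontaneous deamination of 5-methylcytosine at CpG dinucleotides produces
#' C>T transitions on the strand carrying the methylated cytosine. Given the
#' reference-strand trinucleotide context centred on the variant, the call is
#' TRUE when ref C > alt T with the next base G (forward-strand deamination)
#' or ref G > alt A with the previous base C (the reverse-strand cytosine of
#' the same CpG deaminated).
#'
#' @param context 3-base reference-strand context, middle base = `ref`.
#' @param ref,alt single reference / alternate bases.
#' @return list with `is_cpg_transition` (logical) and `strand` ("+", "-",
#'   or NA when not a CpG transition).
#' @export
is_cpg_transition <- function(context, ref, alt) {
  context <- toupper(context); ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(context) != 3 || !grepl("^[ACGT]{3}$", context))
    stop("context must be 3 bases of A/C/G/T")
  if (!grepl("^[ACGT]$", ref) || !grepl("^[ACGT]$", alt))
    stop("ref and alt must be single A/C/G/T bases")
  if (substr(context, 2, 2) != ref)
    stop("context middle base does not match ref")
  if (ref == "C" && alt == "T" && substr(context, 3, 3) == "G")
    return(list(is_cpg_transition = TRUE, strand = "+"))
  if (ref == "G" && alt == "A" && substr(context, 1, 1) == "C")
    return(list(is_cpg_transition = TRUE, strand = "-"))
  list(is_cpg_transition = FALSE, strand = NA_character_)
}
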