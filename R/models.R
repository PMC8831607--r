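#' Define a qualifying-variant model
#'
#' A qualifying model is the rule set deciding which annotated variants may
#' count toward a gene's burden: a minor-allele-frequency ceiling applied in
#' every reference population and both sequencing cohorts (or, for the
#' complementary common-variant model, a floor), the admissible effect
#' classes, an optional PolyPhen-2 HumVar damaging requirement for missense,
#' an optional TraP-score rescue for synonymous/splice-region variants, and
#' the zygosity rule used when collapsing carriers.
#'
#' @param name model identifier.
#' @param maf_max MAF ceiling (inclusive), or `NA` for the common-variant
#'   complement model.
#' @param maf_min MAF floor (exclusive) for the complement model; exactly one
#'   of `maf_max`/`maf_min` must be set.
#' @param effects admissible effect classes besides those reachable through
#'   `trap_min`; LOF classes are taken from `lof` below.
#' @param include_missense logical; admit missense variants.
#' @param require_polyphen_damaging logical; missense must be PolyPhen-2
#'   HumVar "possibly_damaging" or "probably_damaging".
#' @param trap_min TraP-score threshold (inclusive) rescuing synonymous and
#'   splice-region variants, or `NA` for no rescue.
#' @param synonymous_only logical; restrict to synonymous variants (negative
#'   control model).
#' @param zygosity "dominant" (any het/hom carrier) or "recessive" (hom-alt,
#'   or two distinct het qualifying variants in the gene).
#' @param counted logical; whether the model counts toward the study-wide
#'   multiplicity correction.
#' @param lof effect classes treated as loss of function.
#'
#' @return A `qualifying_model` object.
#' @export
qualifying_model <- function(name, maf_max = NA_real_, maf_min = NA_real_,
                             include_missense = FALSE,
                             require_polyphen_damaging = include_missense,
                             trap_min = NA_real_, synonymous_only = FALSE,
                             zygosity = c("dominant", "recessive"),
                             counted = TRUE, lof = lof_effects(),
                             effects = NULL) {
  if (is.na(maf_max) == is.na(maf_min))
    stop("exactly one of maf_max / maf_min must be set")
  if (!is.na(trap_min) && (trap_min < 0 || trap_min > 1))
    stop("trap_min must be in [0,1]")
  structure(list(
    name = name, maf_max = maf_max, maf_min = maf_min,
    include_missense = include_missense,
    require_polyphen_damaging = require_polyphen_damaging,
    trap_min = trap_min, synonymous_only = synonymous_only,
    zygosity = match.arg(zygosity), counted = counted, lof = lof),
    class = "qualifying_model")
}

#' @export
print.qualifying_model <- function(x, ...) {
  freq <- if (!is.na(x$maf_max)) sprintf("MAF <= %g", x$maf_max) else
    sprintf("MAF > %g", x$maf_min)
  cat(sprintf("<qualifying_model> %s: %s, %s%s%s, %s\n", x$name, freq,
              if (x$synonymous_only) "synonymous only" else "LOF",
              if (x$include_missense) " + damaging missense" else "",
              if (!is.na(x$trap_min))
                sprintf(" + syn/splice-region TraP >= %g", x$trap_min) else "",
              x$zygosity))
  invisible(x)
}

#' The built-in qualifying-model registry
#'
#' Nine models: the rare loss-of-function model (MAF <= 1%); its extension
#' with PolyPhen-damaging missense; the further extension rescuing
#' synonymous/splice-region variants with TraP >= 0.2; three frequency tiers
#' of the damaging model (MAF <= 5%, <= 0.1%, <= 0.01%); a recessive model
#' (MAF <= 1%, hom-alt or putative compound het); a synonymous negative
#' control (MAF <= 0.01%); and the complementary common-LOF model (MAF > 1%).
#' The seven non-synonymous models carry `counted = TRUE` and enter the
#' study-wide Bonferroni correction; the synonymous control and common-LOF
#' complement do not.
#'
#' @return Named list of [qualifying_model()] objects.
#' @export
model_registry <- function() {
  list(
    lof = qualifying_model("lof", maf_max = 0.01),
    lof_missense = qualifying_model("lof_missense", maf_max = 0.01,
                                    include_missense = TRUE),
    lof_missense_splicing = qualifying_model(
      "lof_missense_splicing", maf_max = 0.01, include_missense = TRUE,
      trap_min = 0.2),
    maf5 = qualifying_model("maf5", maf_max = 0.05, include_missense = TRUE),
    maf0.1 = qualifying_model("maf0.1", maf_max = 0.001,
                              include_missense = TRUE),
    maf0.01 = qualifying_model("maf0.01", maf_max = 0.0001,
                               include_missense = TRUE),
    recessive = qualifying_model("recessive", maf_max = 0.01,
                                 include_missense = TRUE,
                                 zygosity = "recessive"),
    synonymous_control = qualifying_model(
      "synonymous_control", maf_max = 0.0001, synonymous_only = TRUE,
      counted = FALSE),
    common_lof = qualifying_model("common_lof", maf_min = 0.01,
                                  counted = FALSE))
}

get_model <- function(model) {
  if (inherits(model, "qualifying_model")) return(model)
  reg <- model_registry()
  if (!model %in% names(reg)) stop("unknown model: ", model)
  reg[[model]]
}

# worst-case (largest, minor-allele-folded) frequency across gnomAD
# populations and both internal cohorts; absent gnomAD AF counts as 0
max_maf <- function(variants) {
  afc <- grep("^gnomad_af_", names(variants), value = TRUE)
  afc <- c(afc, intersect(c("case_af", "control_af"), names(variants)))
  if (!length(afc)) stop("no allele-frequency columns found")
  m <- as.matrix(variants[afc])
  m[is.na(m)] <- 0
  m <- pmin(m, 1 - m)   # fold to the minor allele
  apply(m, 1, max)
}

#' Decide qualification of each variant under a model
#'
#' Applies a model's rules to an annotation table and reports, per variant,
#' whether it qualifies and the first failing criterion otherwise. Criteria
#' are checked in the order: site QC, frequency, effect class/predictor.
#' Missense variants missing a PolyPhen label (and synonymous/splice-region
#' variants missing a TraP score) when the model requires one are reported
#' "unannotated" and do not qualify.
#'
#' @param variants annotation data.frame (see [callset()]).
#' @param model a [qualifying_model()] or registry name.
#' @return data.frame with `variant_id`, logical `qualifies`, and `reason`
#'   ("qualifies", "qc_fail", "maf", "effect", "polyphen", "trap",
#'   "unannotated").
#' @export
qualifying_variants <- function(variants, model) {
  m <- get_model(model)
  n <- nrow(variants)
  reason <- rep("qualifies", n)
  ok <- rep(TRUE, n)

  qc <- if ("qc_pass" %in% names(variants)) variants$qc_pass else rep(TRUE, n)
  fail <- !qc
  reason[fail] <- "qc_fail"; ok[fail] <- FALSE

  mm <- max_maf(variants)
  freq_ok <- if (!is.na(m$maf_max)) mm <= m$maf_max else mm > m$maf_min
  fail <- ok & !freq_ok
  reason[fail] <- "maf"; ok[fail] <- FALSE

  eff <- variants$effect
  if (m$synonymous_only) {
    route <- eff == "synonymous"
    why <- ifelse(route, "qualifies", "effect")
  } else {
    is_lof <- eff %in% m$lof
    is_mis <- eff == "missense"
    pp <- if ("polyphen_humvar" %in% names(variants))
      variants$polyphen_humvar else rep("absent", n)
    pp_damaging <- pp %in% c("possibly_damaging", "probably_damaging")
    mis_ok <- m$include_missense &
      (!m$require_polyphen_damaging | pp_damaging)
    is_splice_resc <- eff %in% c("synonymous", "splice_region")
    trap <- if ("trap_score" %in% names(variants))
      variants$trap_score else rep(NA_real_, n)
    trap_ok <- !is.na(m$trap_min) & !is.na(trap) & trap >= m$trap_min

    route <- is_lof | (is_mis & mis_ok) | (is_splice_resc & trap_ok)
    why <- rep("effect", n)
    why[is_mis & m$include_missense & !pp_damaging & pp != "absent"] <-
      "polyphen"
    why[is_mis & m$include_missense & m$require_polyphen_damaging &
          pp == "absent"] <- "unannotated"
    why[is_splice_resc & !is.na(m$trap_min) & !is.na(trap) &
          trap < m$trap_min] <- "trap"
    why[is_splice_resc & !is.na(m$trap_min) & is.na(trap)] <- "unannotated"
    why[route] <- "qualifies"
  }
  fail <- ok & !route
  reason[fail] <- why[fail]; ok[fail] <- FALSE

  data.frame(variant_id = variants$variant_id, qualifies = ok,
             reason = reason, row.names = NULL)
}

#' Single-variant qualification with reason
#'
#' Convenience scalar form of [qualifying_variants()].
#'
#' @param variant one-row annotation data.frame.
#' @param model a [qualifying_model()] or registry name.
#' @return list with `qualifies` and `reason`.
#' @export
is_qualifying <- function(variant, model) {
  r <- qualifying_variants(variant[1, , drop = FALSE], model)
  list(qualifies = r$qualifies[1], reason = r$reason[1])
}

#' Per-gene qualifying genotype calls
#'
#' Collects, for each gene, the non-reference genotype calls at qualifying
#' variants: the raw material of carrier collapsing. Only het/hom-alt calls
#' at covered, QC-passing, qualifying variants are included; genes without a
#' qualifying variant are absent from the result.
#'
#' @param cs a [callset()] (after coverage harmonization).
#' @param model a [qualifying_model()] or registry name.
#' @param retained optional variant IDs surviving harmonization; defaults to
#'   all variants.
#' @return Named list (by gene) of data.frames with `sample_id`,
#'   `variant_id`, `gt` (1 = het, 2 = hom-alt).
#' @export
qualifying_sets <- function(cs, model, retained = NULL) {
  stopifnot(inherits(cs, "callset"))
  qv <- qualifying_variants(cs$variants, model)
  keep <- qv$qualifies
  if (!is.null(retained))
    keep <- keep & (cs$variants$variant_id %in% retained)
  if (any(keep & (is.na(cs$variants$gene) | cs$variants$gene == "")))
    stop("qualifying variant without gene symbol")
  idx <- which(keep)
  if (!length(idx)) return(structure(list(), names = character()))
  sub <- methods::as(cs$geno[, idx, drop = FALSE], "TsparseMatrix")
  tr <- Matrix::summary(sub)
  calls <- data.frame(
    sample_id = cs$samples$sample_id[tr$i],
    variant_id = cs$variants$variant_id[idx][tr$j],
    gene = cs$variants$gene[idx][tr$j],
    gt = tr$x)
  calls <- calls[calls$gt > 0, , drop = FALSE]
  split(calls[c("sample_id", "variant_id", "gt")], calls$gene)
}

#' Write or read a model registry as YAML
#'
#' @param models named list of [qualifying_model()] objects.
#' @param path file path.
#' @return `read_model_registry` returns the named model list.
#' @export
write_model_registry <- function(models, path) {
  yaml::write_yaml(lapply(models, function(m) unclass(m)), path)
  invisible(path)
}

#' @rdname write_model_registry
#' @export
read_model_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) {
    qualifying_model(
      name = m$name,
      maf_max = if (is.null(m$maf_max)) NA_real_ else m$maf_max,
      maf_min = if (is.null(m$maf_min)) NA_real_ else m$maf_min,
      include_missense = isTRUE(m$include_missense),
      require_polyphen_damaging = isTRUE(m$require_polyphen_damaging),
      trap_min = if (is.null(m$trap_min)) NA_real_ else m$trap_min,
      synonymous_only = isTRUE(m$synonymous_only),
      zygosity = m$zygosity, counted = isTRUE(m$counted),
      lof = unlist(m$lof))
  })
}
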