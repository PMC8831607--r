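#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test of independence with fixed margins for the table
#' ((a, b), (c, d)). The two-sided p-value is formed by the
#' minimum-likelihood method: with margins held fixed, the point
#' probabilities of all tables no more probable than the observed one are
#' summed. `fisher_mid_p` additionally returns the mid-p variant (half the
#' observed table's point mass counted), used by the inflation diagnostics
#' where the discreteness of the exact p-value matters.
#'
#' @param a,b,c,d non-negative integer cell counts: case carriers, case
#'   non-carriers, control carriers, control non-carriers.
#' @return `fisher_two_sided`: the two-sided p-value in (0, 1].
#'   `fisher_mid_p`: list with `p` and `p_mid`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  fisher_mid_p(a, b, c, d)$p
}

#' @rdname fisher_two_sided
#' @export
fisher_mid_p <- function(a, b, c, d) {
  for (v in c(a, b, c, d)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("cell counts must be single non-negative integers")
  }
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n)
    return(list(p = 1, p_mid = 1))
  x <- max(0, k - n):min(m, k)
  pr <- stats::dhyper(x, m, n, k)
  po <- stats::dhyper(a, m, n, k)
  p <- sum(pr[pr <= po * (1 + 1e-7)])
  list(p = min(p, 1), p_mid = min(max(p - po / 2, 0), 1))
}

#' Odds ratio of a 2x2 carrier table
#'
#' @param a,b,c,d cell counts as in [fisher_two_sided()].
#' @param method "sample" for the cross-product (a d)/(b c); "cmle" for the
#'   conditional maximum-likelihood estimate under the noncentral
#'   hypergeometric model (the estimator reported by exact-test software).
#' @return The estimate, or `NA` when it is undefined (zero `b c` for the
#'   cross-product; an infinite estimate at a boundary cell for the CMLE).
#' @export
odds_ratio <- function(a, b, c, d, method = c("sample", "cmle")) {
  method <- match.arg(method)
  for (v in c(a, b, c, d))
    if (v < 0 || v != round(v)) stop("cell counts must be non-negative integers")
  if (method == "sample") {
    if (b * c == 0) return(NA_real_)
    return((a * d) / (b * c))
  }
  est <- unname(stats::fisher.test(matrix(c(a, b, c, d), 2,
                                          byrow = TRUE))$estimate)
  if (!is.finite(est)) NA_real_ else est
}

# Woolf (log cross-product) confidence interval; NA at any zero cell
or_woolf_ci <- function(a, b, c, d, conf = 0.95) {
  if (min(a, b, c, d) == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lor <- log((a * d) / (b * c))
  exp(lor + c(-1, 1) * z * se)
}

#' Bonferroni significance thresholds
#'
#' Genome-wide threshold 0.05/G for G tested genes, and study-wide threshold
#' 0.05/(M G) after additionally correcting for M collapsing models.
#'
#' @param n_genes number of genes in the tested universe (>= 1).
#' @param n_models number of models counted in the study-wide correction.
#' @param alpha family-wise error rate before correction.
#' @return list of class `threshold_spec` with `n_genes`, `n_models`,
#'   `alpha_genome`, `alpha_study`.
#' @export
collapsing_thresholds <- function(n_genes, n_models = 7, alpha = 0.05) {
  if (n_genes < 1 || n_models < 1) stop("n_genes and n_models must be >= 1")
  structure(list(n_genes = n_genes, n_models = n_models,
                 alpha_genome = alpha / n_genes,
                 alpha_study = alpha / (n_models * n_genes)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> G=%d genes, M=%d models: genome-wide %.3g, study-wide %.3g\n",
              x$n_genes, x$n_models, x$alpha_genome, x$alpha_study))
  invisible(x)
}

# carrier indicator per sample for one gene's qualifying calls
gene_carriers <- function(calls, zygosity) {
  if (zygosity == "dominant") return(unique(calls$sample_id))
  hom <- unique(calls$sample_id[calls$gt == 2])
  het <- calls[calls$gt == 1, , drop = FALSE]
  nhet <- table(unique(het[c("sample_id", "variant_id")])$sample_id)
  union(hom, names(nhet)[nhet >= 2])
}

burden_row <- function(gene, a, n1, c, n2, or_method, thresholds) {
  fp <- fisher_mid_p(a, n1 - a, c, n2 - c)
  ci <- or_woolf_ci(a, n1 - a, c, n2 - c)
  data.frame(
    gene = gene, case_carriers = a, cases_total = n1,
    control_carriers = c, controls_total = n2,
    case_freq = a / n1, control_freq = c / n2,
    p_value = fp$p, p_mid = fp$p_mid,
    odds_ratio = odds_ratio(a, n1 - a, c, n2 - c, or_method),
    or_ci_lower = ci[1], or_ci_upper = ci[2],
    genome_wide = fp$p < thresholds$alpha_genome,
    study_wide = fp$p < thresholds$alpha_study,
    row.names = NULL)
}

#' Collapse qualifying calls and run the exome-wide burden scan
#'
#' Reduces each gene's qualifying variants to a per-sample carrier indicator
#' (a sample carries if it has at least one qualifying het/hom-alt call under
#' the dominant rule; hom-alt or two distinct het qualifying variants under
#' the recessive rule), forms the 2x2 carrier table against case/control
#' status, and applies the two-tailed Fisher exact test per gene. Genes in
#' the universe without qualifying variants are reported with zero carriers
#' and p = 1. Results are sorted by ascending p-value, ties broken by gene
#' symbol.
#'
#' @param cs a [callset()].
#' @param model a [qualifying_model()] or registry name.
#' @param gene_universe optional character vector of tested genes (the CCDS
#'   list in the study design); defaults to the genes present in the
#'   annotation table. The Bonferroni thresholds use its length unless
#'   `thresholds` is supplied.
#' @param thresholds a [collapsing_thresholds()] object.
#' @param retained optional variant IDs surviving coverage harmonization.
#' @param or_method odds-ratio estimator for the result table.
#' @return data.frame of class `burden_result`, one row per gene.
#' @export
collapse_and_test <- function(cs, model, gene_universe = NULL,
                              thresholds = NULL, retained = NULL,
                              or_method = "sample") {
  m <- get_model(model)
  if (is.null(gene_universe))
    gene_universe <- sort(unique(cs$variants$gene))
  if (is.null(thresholds))
    thresholds <- collapsing_thresholds(length(gene_universe))
  sz <- cohort_sizes(cs)
  qs <- qualifying_sets(cs, m, retained = retained)
  stray <- setdiff(names(qs), gene_universe)
  if (length(stray))
    stop("qualifying variants in genes outside the universe: ",
         paste(stray, collapse = ", "))
  is_case <- stats::setNames(cs$samples$status == "case",
                             cs$samples$sample_id)
  rows <- lapply(gene_universe, function(g) {
    calls <- qs[[g]]
    if (is.null(calls) || !nrow(calls))
      return(burden_row(g, 0L, sz[["cases"]], 0L, sz[["controls"]],
                        or_method, thresholds))
    unknown <- setdiff(calls$sample_id, cs$samples$sample_id)
    if (length(unknown)) stop("qualifying call for unknown sample")
    carr <- gene_carriers(calls, m$zygosity)
    a <- sum(is_case[carr]); c <- length(carr) - a
    burden_row(g, a, sz[["cases"]], c, sz[["controls"]],
               or_method, thresholds)
  })
  res <- do.call(rbind, rows)
  res$model <- m$name
  res <- res[order(res$p_value, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("burden_result", "data.frame")
  attr(res, "thresholds") <- thresholds
  res
}

#' Single-variant carrier test
#'
#' The same exact-test machinery applied to one variant's carrier counts
#' (used for per-variant breakdowns of a gene's burden signal).
#'
#' @param a,n1,c,n2 case carriers, cases total, control carriers, controls
#'   total.
#' @param or_method odds-ratio estimator.
#' @return One-row data.frame with counts, frequencies, p-value and OR.
#' @export
carrier_test <- function(a, n1, c, n2, or_method = "sample") {
  thr <- collapsing_thresholds(1)
  out <- burden_row(NA_character_, a, n1, c, n2, or_method, thr)
  out$gene <- NULL; out$genome_wide <- NULL; out$study_wide <- NULL
  out
}

#' Per-variant burden breakdown
#'
#' Carrier counts and exact tests for every qualifying variant of a model in
#' a call set (optionally restricted to one gene).
#'
#' @param cs a [callset()].
#' @param model a [qualifying_model()] or registry name.
#' @param gene optional gene symbol filter.
#' @param retained optional harmonization-retained variant IDs.
#' @return data.frame with one row per qualifying variant.
#' @export
per_variant_test <- function(cs, model, gene = NULL, retained = NULL) {
  qs <- qualifying_sets(cs, model, retained = retained)
  if (!is.null(gene)) qs <- qs[intersect(names(qs), gene)]
  sz <- cohort_sizes(cs)
  is_case <- stats::setNames(cs$samples$status == "case",
                             cs$samples$sample_id)
  rows <- lapply(names(qs), function(g) {
    calls <- qs[[g]]
    do.call(rbind, lapply(split(calls, calls$variant_id), function(cv) {
      sm <- unique(cv$sample_id)
      a <- sum(is_case[sm])
      cbind(data.frame(gene = g, variant_id = cv$variant_id[1]),
            carrier_test(a, sz[["cases"]], length(sm) - a, sz[["controls"]]))
    }))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res <- res[order(res$p_value, res$variant_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full collapsing pipeline over one or more models
#'
#' End-to-end scan: per-site coverage harmonization, qualifying-variant
#' selection, per-gene carrier collapsing and exact testing, for each
#' requested model.
#'
#' @param cs a [callset()].
#' @param models character vector of registry names or list of
#'   [qualifying_model()] objects.
#' @param alpha_coverage coverage-harmonization exclusion threshold.
#' @param gene_universe,thresholds,or_method passed to [collapse_and_test()].
#' @return Named list of `burden_result` tables, plus attribute
#'   `harmonization` (the [harmonize_sites()] output).
#' @export
run_burden_scan <- function(cs, models = c("lof", "lof_missense",
                                           "lof_missense_splicing"),
                            alpha_coverage = 0.01, gene_universe = NULL,
                            thresholds = NULL, or_method = "sample") {
  harm <- harmonize_sites(cs, alpha = alpha_coverage)
  out <- lapply(models, function(m)
    collapse_and_test(cs, m, gene_universe = gene_universe,
                      thresholds = thresholds, retained = harm$retained,
                      or_method = or_method))
  names(out) <- vapply(models, function(m) get_model(m)$name, "")
  attr(out, "harmonization") <- harm
  out
}
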