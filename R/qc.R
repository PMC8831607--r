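#' Sample-level quality and relatedness filtering
#'
#' Applies the cohort's sample gates: contamination strictly greater than
#' `max_contamination` excludes a sample; a CCDS 10x-coverage fraction at or
#' below `min_ccds10x` excludes a sample (eligibility requires > 87% of CCDS
#' covered at 10x); and from every group of related samples (kinship pairs up
#' to third degree) a maximal set of mutually unrelated samples is kept.
#'
#' Relatedness pruning solves the maximum independent set exactly (branch and
#' bound) within each kinship component of up to `exact_limit` samples; larger
#' components fall back to greedy highest-degree removal. Ties are broken by
#' sample ID order, so the result is deterministic.
#'
#' @param metrics data.frame with columns `sample_id`, `contamination`,
#'   `ccds10x_frac`.
#' @param kinship optional data.frame of related pairs, columns `id1`, `id2`.
#' @param max_contamination exclusion threshold (exclusive) on the
#'   contamination fraction; default 0.08.
#' @param min_ccds10x minimum (exclusive) CCDS fraction covered at 10x;
#'   default 0.87.
#' @param exact_limit largest kinship component solved exactly.
#'
#' @return list with `kept` (character vector of retained sample IDs) and
#'   `exclusions` (data.frame `sample_id`, `reason`).
#' @export
filter_samples <- function(metrics, kinship = NULL,
                           max_contamination = 0.08, min_ccds10x = 0.87,
                           exact_limit = 25L) {
  stopifnot(is.data.frame(metrics),
            all(c("sample_id", "contamination", "ccds10x_frac") %in%
                  names(metrics)))
  if (anyDuplicated(metrics$sample_id)) stop("duplicate sample IDs")
  if (any(metrics$contamination < 0 | metrics$contamination > 1) ||
      any(metrics$ccds10x_frac < 0 | metrics$ccds10x_frac > 1))
    stop("metric fractions must lie in [0,1]")

  excl <- data.frame(sample_id = character(), reason = character())
  bad_cont <- metrics$sample_id[metrics$contamination > max_contamination]
  bad_cov <- setdiff(
    metrics$sample_id[metrics$ccds10x_frac <= min_ccds10x], bad_cont)
  excl <- rbind(excl,
                data.frame(sample_id = bad_cont,
                           reason = rep("contamination", length(bad_cont))),
                data.frame(sample_id = bad_cov,
                           reason = rep("low_ccds_coverage", length(bad_cov))))
  kept <- setdiff(metrics$sample_id, excl$sample_id)

  if (!is.null(kinship) && nrow(kinship)) {
    stopifnot(all(c("id1", "id2") %in% names(kinship)))
    unknown <- setdiff(c(kinship$id1, kinship$id2), metrics$sample_id)
    if (length(unknown))
      stop("kinship pairs reference unknown samples: ",
           paste(unknown, collapse = ", "))
    kin <- kinship[kinship$id1 %in% kept & kinship$id2 %in% kept, ,
                   drop = FALSE]
    if (nrow(kin)) {
      g <- igraph::graph_from_data_frame(kin, directed = FALSE,
                                         vertices = sort(kept))
      keep_rel <- max_unrelated_set(g, exact_limit)
      rel_excl <- setdiff(kept, keep_rel)
      excl <- rbind(excl, data.frame(
        sample_id = rel_excl, reason = rep("relatedness", length(rel_excl))))
      kept <- keep_rel
    }
  }
  kept <- metrics$sample_id[metrics$sample_id %in% kept]
  list(kept = kept, exclusions = excl)
}

# maximal set of mutually unrelated samples across kinship components
max_unrelated_set <- function(g, exact_limit) {
  comp <- igraph::components(g)
  kept <- character()
  for (cid in seq_len(comp$no)) {
    verts <- names(comp$membership)[comp$membership == cid]
    if (length(verts) == 1) { kept <- c(kept, verts); next }
    sub <- igraph::induced_subgraph(g, verts)
    nm <- sort(igraph::V(sub)$name)
    adj <- lapply(nm, function(v)
      sort(names(igraph::neighbors(sub, v))))
    names(adj) <- nm
    kept <- c(kept, if (length(nm) <= exact_limit)
      mis_exact(nm, adj) else mis_greedy(nm, adj))
  }
  sort(kept)
}

# exact maximum independent set; deterministic branch on max-degree vertex,
# lexicographic preference between equally sized solutions
mis_exact <- function(verts, adj) {
  if (!length(verts)) return(character())
  deg <- vapply(verts, function(v) length(intersect(adj[[v]], verts)), 0L)
  if (all(deg == 0)) return(verts)
  v <- verts[order(-deg, verts)][1]
  rest <- setdiff(verts, v)
  a <- mis_exact(rest, adj)                               # exclude v
  b <- c(v, mis_exact(setdiff(rest, adj[[v]]), adj))      # include v
  better <- if (length(b) != length(a)) length(b) > length(a) else
    paste(sort(b), collapse = "|") < paste(sort(a), collapse = "|")
  if (better) b else a
}

mis_greedy <- function(verts, adj) {
  repeat {
    deg <- vapply(verts, function(v) length(intersect(adj[[v]], verts)), 0L)
    if (all(deg == 0)) return(verts)
    drop <- verts[order(-deg, verts)][1]
    verts <- setdiff(verts, drop)
  }
}

#' Variant-level quality-control verdict
#'
#' Evaluates the site/genotype QC rule set: pass requires quality >= 30,
#' quality-by-depth >= 2, genotype quality >= 20, read-position rank sum
#' >= -3, mapping quality >= 40, mapping-quality rank sum > -10, depth >= 10,
#' Fisher strand bias <= 60 for SNVs (<= 200 for indels), an alternate-allele
#' ratio >= 0.25 for heterozygous calls, and no EVS failure flag. The verdict
#' is a pure conjunction: every rule is evaluated and all failed rules are
#' reported. Rank-sum statistics may be absent (common when all reads carry
#' one allele); absence is not evidence of bias and passes that rule.
#'
#' @param metrics data.frame with columns `qual`, `qd`, `gq`,
#'   `read_pos_rank_sum`, `mq`, `mq_rank_sum`, `depth`, `fs`,
#'   `alt_allele_ratio` (NA for non-het calls), `is_indel`, `evs_failure`.
#' @return data.frame with logical `pass` and character `failed_rules`
#'   (comma-separated, empty when passing), one row per input row.
#' @export
apply_variant_qc <- function(metrics) {
  need <- c("qual", "qd", "gq", "read_pos_rank_sum", "mq", "mq_rank_sum",
            "depth", "fs", "alt_allele_ratio", "is_indel", "evs_failure")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("missing QC metric columns: ",
                         paste(miss, collapse = ", "))
  if (any(metrics$depth < 0, na.rm = TRUE)) stop("negative depth")
  if (any(metrics$alt_allele_ratio < 0 | metrics$alt_allele_ratio > 1,
          na.rm = TRUE))
    stop("alt_allele_ratio outside [0,1]")

  rules <- list(
    qual = metrics$qual >= 30,
    qd = metrics$qd >= 2,
    gq = metrics$gq >= 20,
    read_pos_rank_sum = is.na(metrics$read_pos_rank_sum) |
      metrics$read_pos_rank_sum >= -3,
    mq = metrics$mq >= 40,
    mq_rank_sum = is.na(metrics$mq_rank_sum) | metrics$mq_rank_sum > -10,
    depth = metrics$depth >= 10,
    fs = metrics$fs <= ifelse(metrics$is_indel, 200, 60),
    allele_balance = is.na(metrics$alt_allele_ratio) |
      metrics$alt_allele_ratio >= 0.25,
    evs = !metrics$evs_failure)
  ok <- Reduce(`&`, rules)
  failed <- apply(!do.call(cbind, rules), 1, function(z)
    paste(names(rules)[z], collapse = ","))
  data.frame(pass = ok, failed_rules = failed, row.names = NULL)
}

#' Exact two-sided test of coverage/status independence at one site
#'
#' Tests whether being covered (depth >= 10) at a site is independent of
#' case/control status. Under the pooled null, the covered-sample count of the
#' tested cohort is Binomial(n, p-hat) with p-hat the pooled covered fraction;
#' the two-sided p-value sums all binomial point masses no larger than that of
#' the observed count (minimum-likelihood method).
#'
#' @param covered_cases,covered_controls covered-sample counts.
#' @param n_cases,n_controls cohort sizes (> 0).
#' @param side which cohort's count is tested against the pooled rate.
#' @return Two-sided p-value in (0, 1].
#' @export
coverage_independence_test <- function(covered_cases, n_cases,
                                       covered_controls, n_controls,
                                       side = c("cases", "controls")) {
  side <- match.arg(side)
  if (n_cases <= 0 || n_controls <= 0) stop("zero-size cohort")
  if (covered_cases < 0 || covered_cases > n_cases ||
      covered_controls < 0 || covered_controls > n_controls)
    stop("covered counts must lie in [0, n]")
  phat <- (covered_cases + covered_controls) / (n_cases + n_controls)
  k <- if (side == "cases") covered_cases else covered_controls
  n <- if (side == "cases") n_cases else n_controls
  d <- stats::dbinom(0:n, n, phat)
  p <- sum(d[d <= d[k + 1] * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Coverage harmonization across a call set
#'
#' Applies [coverage_independence_test()] at every site and eliminates sites
#' whose coverage is associated with case/control status at `alpha` or lower,
#' so that differential coverage cannot masquerade as differential burden.
#'
#' @param cs a [callset()].
#' @param alpha exclusion threshold on the two-sided p-value (site excluded
#'   iff p <= alpha); default 0.01.
#' @param side passed to [coverage_independence_test()].
#' @return list with `retained` (variant IDs), `excluded` (data.frame
#'   `variant_id`, `p`), and `p` (named vector of all per-site p-values).
#' @export
harmonize_sites <- function(cs, alpha = 0.01, side = "cases") {
  stopifnot(inherits(cs, "callset"))
  cc <- covered_counts(cs)
  sz <- cohort_sizes(cs)
  # fully covered sites are independent by construction (p = 1); only
  # sites with any uncovered sample need the exact test
  p <- rep(1, nrow(cc))
  todo <- which(cc$covered_cases < sz[["cases"]] |
                  cc$covered_controls < sz[["controls"]])
  p[todo] <- vapply(todo, function(i)
    coverage_independence_test(cc$covered_cases[i], sz[["cases"]],
                               cc$covered_controls[i], sz[["controls"]],
                               side = side), 0)
  names(p) <- cc$variant_id
  out <- p <= alpha
  list(retained = cc$variant_id[!out],
       excluded = data.frame(variant_id = cc$variant_id[out], p = p[out],
                             row.names = NULL),
       p = p)
}
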