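#' Simulation configuration for a synthetic case/control exome cohort
#'
#' Defines the cohort the simulator generates. Defaults reproduce the study
#' conditions the package's calibration suites run under: 849 cases versus
#' 15,640 controls, 2,000 genes, and a rare-skewed allele-frequency spectrum
#' (Beta(0.2, 200)), with gene-to-gene variation in variant density modelled
#' by a negative-binomial count (genes differ widely in length and hence in
#' the number of distinct rare variants they harbor in a cohort of ~16k
#' exomes).
#'
#' @param n_cases,n_controls cohort sizes (>= 1).
#' @param n_genes number of simulated genes.
#' @param variants_per_gene mean number of distinct variants per gene; the
#'   realized count is NegBin(`variants_per_gene`, size = `gene_dispersion`).
#' @param gene_dispersion negative-binomial size parameter for per-gene
#'   variant counts (smaller = more overdispersed).
#' @param effect_class_weights named probability vector over
#'   [effect_classes()] (any subset); must sum to 1.
#' @param maf_beta shape parameters of the Beta allele-frequency spectrum.
#' @param enrichments data.frame with columns `gene`, `case_carrier_freq`,
#'   `control_carrier_freq`, `model` describing genes with an implanted
#'   case/control carrier-frequency difference. Carrier status is drawn
#'   Bernoulli per sample; each implanted carrier receives exactly one
#'   qualifying variant for the named model (carrier collapsing makes
#'   per-carrier multiplicity irrelevant).
#' @param recessive_implant for enrichments under the recessive model:
#'   "hom" implants hom-alt carriers, "compound_het" implants two distinct
#'   het variants per carrier.
#' @param populations gnomAD-style population labels to emit AF columns for.
#' @param missing_rate per-genotype no-call rate (default 0).
#' @param seed integer RNG seed; the one generator drives all draws and is
#'   recorded in the output metadata.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 849, n_controls = 15640, n_genes = 2000,
                       variants_per_gene = 75, gene_dispersion = 2,
                       effect_class_weights = c(
                         stop_gained = 0.06, frameshift = 0.06,
                         splice_acceptor = 0.02, splice_donor = 0.02,
                         missense = 0.50, synonymous = 0.29,
                         splice_region = 0.05),
                       maf_beta = c(0.2, 200),
                       enrichments = NULL,
                       recessive_implant = c("hom", "compound_het"),
                       populations = c("nfe", "afr", "amr", "eas", "sas"),
                       missing_rate = 0, seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("cohort sizes must be >= 1")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (abs(sum(effect_class_weights) - 1) > 1e-8)
    stop("effect_class_weights must sum to 1")
  if (!all(names(effect_class_weights) %in% effect_classes()))
    stop("unknown effect class in weights")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  if (!is.null(enrichments)) {
    stopifnot(is.data.frame(enrichments),
              all(c("gene", "case_carrier_freq", "control_carrier_freq",
                    "model") %in% names(enrichments)))
    if (any(enrichments$case_carrier_freq < 0 | enrichments$case_carrier_freq > 1 |
            enrichments$control_carrier_freq < 0 | enrichments$control_carrier_freq > 1))
      stop("carrier frequencies must be in [0,1]")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), variants_per_gene = variants_per_gene,
    gene_dispersion = gene_dispersion,
    effect_class_weights = effect_class_weights, maf_beta = maf_beta,
    enrichments = enrichments,
    recessive_implant = match.arg(recessive_implant),
    populations = populations, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "sim_config")
}

# default passing site-QC metrics for simulated variants
qc_metric_defaults <- function(n, is_indel = rep(FALSE, n)) {
  data.frame(qual = 60, qd = 8, gq = 90, read_pos_rank_sum = 0, mq = 60,
             mq_rank_sum = 0, depth = 40, fs = 5,
             alt_allele_ratio = 0.5, is_indel = is_indel,
             evs_failure = FALSE)[rep(1, n), , drop = FALSE]
}

#' Simulate an annotated case/control cohort
#'
#' Draws a synthetic cohort with the statistical structure a collapsing
#' analysis assumes: per-gene variant counts, rare-skewed population allele
#' frequencies, effect-class labels with PolyPhen/TraP annotations, and
#' carrier genotypes. Genes without an implanted enrichment have identical
#' expected carrier frequency in cases and controls; enriched genes draw
#' carrier indicators Bernoulli(`case_carrier_freq`) in cases and
#' Bernoulli(`control_carrier_freq`) in controls, each implanted carrier
#' receiving one qualifying variant (heterozygous except under the recessive
#' implant modes). Output is deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return A [callset()] with fully populated annotation table; the seed is
#'   recorded in `$meta`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  samples <- data.frame(
    sample_id = c(sprintf("case_%05d", seq_len(config$n_cases)),
                  sprintf("ctrl_%05d", seq_len(config$n_controls))),
    status = rep(c("case", "control"), c(config$n_cases, config$n_controls)))

  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  if (!is.null(config$enrichments)) {
    ei <- seq_len(nrow(config$enrichments))
    genes[ei] <- config$enrichments$gene
    if (anyDuplicated(genes)) stop("enriched gene IDs collide")
  }

  k <- stats::rnbinom(config$n_genes, size = config$gene_dispersion,
                      mu = config$variants_per_gene)
  k <- pmax(k, 1L)
  # an enriched gene's carrier status is exactly the declared Bernoulli
  # draw: its content is the implant alone, with no background variants
  if (!is.null(config$enrichments))
    k[seq_len(nrow(config$enrichments))] <- 0L
  V <- sum(k)
  gene_of <- rep(genes, k)

  eff <- sample(names(config$effect_class_weights), V, replace = TRUE,
                prob = config$effect_class_weights)
  af <- stats::rbeta(V, config$maf_beta[1], config$maf_beta[2])

  ann <- data.frame(
    variant_id = sprintf("var%06d", seq_len(V)),
    chrom = "chr1",
    pos = seq_len(V) * 100L,
    ref = sample(c("A", "C", "G", "T"), V, replace = TRUE),
    alt = "T", gene = gene_of, effect = eff, stringsAsFactors = FALSE)
  ann$alt <- ifelse(ann$ref == "T", "A", ann$alt)

  # population AFs jitter around the drawn spectrum value
  for (p in config$populations)
    ann[[paste0("gnomad_af_", p)]] <-
      pmin(1, af * stats::runif(V, 0.5, 1.5))

  ann$polyphen_humvar <- "absent"
  mi <- which(eff == "missense")
  ann$polyphen_humvar[mi] <- sample(
    c("benign", "possibly_damaging", "probably_damaging", "absent"),
    length(mi), replace = TRUE, prob = c(0.45, 0.20, 0.30, 0.05))
  ann$trap_score <- NA_real_
  ti <- which(eff %in% c("synonymous", "splice_region"))
  ann$trap_score[ti] <- stats::rbeta(length(ti), 0.4, 3)

  ann <- cbind(ann, qc_metric_defaults(V, is_indel = eff == "frameshift"))
  ann$qc_pass <- TRUE

  # background genotypes: carrier probability ~ 2 * AF, same in both cohorts
  pcar <- pmin(1, 2 * af)
  ncar <- stats::rbinom(V, n, pcar)
  j <- rep.int(seq_len(V), ncar)
  i <- unlist(lapply(seq_len(V), function(v)
    if (ncar[v] > 0) sample.int(n, ncar[v]) else integer()), use.names = FALSE)
  x <- rep.int(1, length(i))
  # occasional hom-alt in the background, proportional to AF
  if (length(i)) {
    hom <- stats::runif(length(i)) < af[j]
    x[hom] <- 2
  }

  # implanted enrichments: each implanted carrier receives its own private
  # qualifying variant (keeps every variant individually rare, as in real
  # gene burdens spread over many distinct variants); compound-het carriers
  # receive two
  if (!is.null(config$enrichments)) {
    for (e in seq_len(nrow(config$enrichments))) {
      en <- config$enrichments[e, ]
      carrier <- c(stats::runif(config$n_cases) < en$case_carrier_freq,
                   stats::runif(config$n_controls) < en$control_carrier_freq)
      ci <- which(carrier)
      nc <- length(ci)
      if (nc == 0) next
      per <- if (identical(en$model, "recessive") &&
                 config$recessive_implant == "compound_het") 2L else 1L
      gt <- if (identical(en$model, "recessive") &&
                config$recessive_implant == "hom") 2 else 1
      nv_new <- per * nc
      imp <- do.call(rbind, lapply(seq_len(nv_new), function(kk)
        implant_variant_row(en$model, nrow(ann) + kk)))
      imp$gene <- en$gene
      for (p in config$populations)
        imp[[paste0("gnomad_af_", p)]] <- imp$.af_template
      imp$.af_template <- NULL
      newj <- nrow(ann) + seq_len(nv_new)
      ann <- rbind(ann, imp[names(ann)])
      i <- c(i, rep(ci, each = per))
      j <- c(j, newj)
      x <- c(x, rep.int(gt, nv_new))
    }
  }

  Vtot <- nrow(ann)
  # collapse duplicate (sample, variant) draws, keeping the larger genotype
  ord <- order(j, i, -x)
  dup <- duplicated(cbind(j, i)[ord, , drop = FALSE])
  keep <- ord[!dup]
  geno <- sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(n, Vtot))

  mis <- NULL
  if (config$missing_rate > 0) {
    nmis <- stats::rbinom(Vtot, n, config$missing_rate)
    jm <- rep.int(seq_len(Vtot), nmis)
    im <- unlist(lapply(seq_len(Vtot), function(v)
      if (nmis[v] > 0) sample.int(n, nmis[v]) else integer()),
      use.names = FALSE)
    mis <- sparseMatrix(i = im, j = jm, dims = c(n, Vtot))
    geno <- zero_at(geno, mis)   # a no-call stores 0 in the genotype matrix
  }

  cs <- callset(samples, ann, geno, missing = mis,
                meta = list(seed = config$seed, config = config))
  update_internal_af(cs)
}

# zero genotype entries at the cells flagged in a sparse pattern mask
zero_at <- function(geno, mask) {
  tr <- Matrix::summary(methods::as(mask, "TsparseMatrix"))
  if (nrow(tr)) geno[cbind(tr$i, tr$j)] <- 0
  methods::as(methods::as(Matrix::drop0(geno), "CsparseMatrix"),
              "generalMatrix")
}

drop0_pattern <- function(m) methods::as(Matrix::drop0(m), "nsparseMatrix")

# annotation row for an implanted qualifying variant of a given model
implant_variant_row <- function(model, idx) {
  eff <- switch(model,
    lof = , maf5 = , maf0.1 = , maf0.01 = , recessive = ,
    common_lof = "stop_gained",
    lof_missense = "missense",
    lof_missense_splicing = "splice_region",
    synonymous_control = "synonymous",
    stop("no implant rule for model: ", model))
  af <- if (identical(model, "common_lof")) 0.05 else
    if (identical(model, "maf0.01")) 5e-5 else
    if (identical(model, "maf0.1")) 5e-4 else 1e-3
  row <- data.frame(
    variant_id = sprintf("imp%06d", idx), chrom = "chr1",
    pos = 10000000L + idx, ref = "C", alt = "T",
    gene = NA_character_, effect = eff,
    polyphen_humvar = if (eff == "missense") "probably_damaging" else "absent",
    trap_score = if (eff %in% c("synonymous", "splice_region")) 0.55 else NA_real_,
    .af_template = af, stringsAsFactors = FALSE)
  cbind(row, qc_metric_defaults(1), qc_pass = TRUE)
}

#' Build a call set reproducing an exact 2x2 carrier table
#'
#' Constructs a minimal cohort in which collapsing `gene_id` yields exactly
#' the table (`a`, `n1 - a`, `c`, `n2 - c`): the first `a` cases and first
#' `c` controls are carriers, each of their own qualifying variant (so every
#' variant stays individually rare, as in real cohorts where a gene's burden
#' is spread over many distinct variants). Used to replay printed
#' contingency tables through the full pipeline bit-exactly.
#'
#' @param a,c case / control carrier counts.
#' @param n1,n2 case / control cohort sizes.
#' @param gene_id gene symbol for the fixture variant.
#' @param model qualifying model the fixture variant must satisfy
#'   (see [model_registry()]).
#' @return A [callset()].
#' @export
make_fixture_from_counts <- function(a, n1, c, n2, gene_id = "GENE",
                                     model = "lof") {
  stopifnot(a >= 0, c >= 0, n1 >= 1, n2 >= 1)
  if (a > n1 || c > n2) stop("carrier count exceeds cohort size")
  samples <- data.frame(
    sample_id = c(sprintf("case_%05d", seq_len(n1)),
                  sprintf("ctrl_%05d", seq_len(n2))),
    status = rep(c("case", "control"), c(n1, n2)))
  carriers <- c(seq_len(a), if (c > 0) n1 + seq_len(c))
  nv <- max(1L, length(carriers))
  ann <- do.call(rbind, lapply(seq_len(nv), implant_variant_row,
                               model = model))
  ann$gene <- gene_id
  ann$pos <- 10000000L + seq_len(nv)
  # fixtures replay printed tables whose variants are known rare: pin the
  # frequency annotations (absent from reference populations) instead of
  # deriving them from the miniature cohort, where a single carrier can
  # already exceed a rare-MAF ceiling
  for (p in c("nfe", "afr", "amr", "eas", "sas"))
    ann[[paste0("gnomad_af_", p)]] <- 0
  if (identical(model, "common_lof"))
    ann[[paste0("gnomad_af_", "nfe")]] <- ann$.af_template
  ann$.af_template <- NULL
  ann$case_af <- 0
  ann$control_af <- 0
  gt <- if (identical(model, "recessive")) 2 else 1
  geno <- sparseMatrix(i = carriers, j = seq_along(carriers),
                       x = rep.int(gt, length(carriers)),
                       dims = c(n1 + n2, nv))
  callset(samples, ann, geno)
}

#' Implant case/control coverage imbalance at designated sites
#'
#' Marks `n_sites` variant sites as covered in each case sample with
#' probability `case_cover_frac` and in each control with
#' `control_cover_frac`; all remaining sites stay fully covered. Genotype
#' calls at newly uncovered cells are cleared and flagged missing, keeping
#' the covered-implies-called invariant.
#'
#' @param cs a [callset()].
#' @param n_sites number of sites to perturb (first `n_sites` variants are
#'   used unless `sites` is given).
#' @param case_cover_frac,control_cover_frac per-sample coverage
#'   probabilities in \[0,1\].
#' @param seed RNG seed for the coverage draws.
#' @param sites optional explicit variant IDs to perturb.
#' @return The perturbed `callset`.
#' @export
simulate_coverage_imbalance <- function(cs, n_sites, case_cover_frac,
                                        control_cover_frac, seed = 1L,
                                        sites = NULL) {
  stopifnot(inherits(cs, "callset"))
  if (any(c(case_cover_frac, control_cover_frac) < 0) ||
      any(c(case_cover_frac, control_cover_frac) > 1))
    stop("coverage fractions must be in [0,1]")
  if (is.null(sites)) {
    if (n_sites > nrow(cs$variants)) stop("n_sites exceeds number of sites")
    sites <- cs$variants$variant_id[seq_len(n_sites)]
  }
  sj <- match(sites, cs$variants$variant_id)
  if (anyNA(sj)) stop("unknown site ID")
  set.seed(seed)
  n <- nrow(cs$samples)
  is_case <- cs$samples$status == "case"
  p_cover <- ifelse(is_case, case_cover_frac, control_cover_frac)
  im <- integer(); jm <- integer()
  for (v in sj) {
    unc <- which(stats::runif(n) >= p_cover)
    im <- c(im, unc); jm <- c(jm, rep.int(v, length(unc)))
  }
  unc_new <- sparseMatrix(i = im, j = jm, dims = dim(cs$geno))
  uncovered <- cs$uncovered | unc_new
  missing <- cs$missing | drop0_pattern(unc_new * (cs$geno != 0))
  geno <- zero_at(cs$geno, unc_new)
  cs2 <- callset(cs$samples, cs$variants, geno,
                 missing = missing, uncovered = uncovered, meta = cs$meta)
  update_internal_af(cs2)
}
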