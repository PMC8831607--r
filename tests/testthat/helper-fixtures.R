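# annotation-row builder for model tests: rare, QC-passing SNV by default
toy_variant <- function(effect = "stop_gained", af = 0.004,
                        case_af = 0.001, control_af = 0.001,
                        polyphen = "absent", trap = NA_real_,
                        qc_pass = TRUE, gene = "GENE1", id = "v1") {
  data.frame(
    variant_id = id, chrom = "chr1", pos = 100L, ref = "C", alt = "T",
    gene = gene, effect = effect,
    gnomad_af_nfe = af, gnomad_af_afr = af, gnomad_af_eas = af,
    case_af = case_af, control_af = control_af,
    polyphen_humvar = polyphen, trap_score = trap, qc_pass = qc_pass,
    stringsAsFactors = FALSE)
}

# minimal callset: genotype triplets (sample index, variant index, gt)
toy_callset <- function(n_cases, n_controls, variants, geno_triplets) {
  n <- n_cases + n_controls
  samples <- data.frame(
    sample_id = c(sprintf("case%03d", seq_len(n_cases)),
                  sprintf("ctrl%03d", seq_len(n_controls))),
    status = rep(c("case", "control"), c(n_cases, n_controls)))
  geno <- Matrix::sparseMatrix(
    i = geno_triplets$i, j = geno_triplets$j, x = geno_triplets$x,
    dims = c(n, nrow(variants)))
  rvburden::callset(samples, variants, geno)
}

# passing variant-QC metric row; override single fields to force failures
qc_row <- function(...) {
  row <- data.frame(qual = 60, qd = 8, gq = 90, read_pos_rank_sum = 0,
                    mq = 60, mq_rank_sum = 0, depth = 40, fs = 5,
                    alt_allele_ratio = 0.5, is_indel = FALSE,
                    evs_failure = FALSE)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# independent minimum-likelihood two-sided FET oracle built from choose();
# enumerates every table with the observed margins
fet_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n || m + n == 0) return(1)
  xs <- max(0, k - n):min(m, k)
  pr <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  po <- pr[match(a, xs)]
  min(1, sum(pr[pr <= po * (1 + 1e-7)]))
}

# brute-force maximum independent set size by subset enumeration (<= 20 nodes)
mis_bruteforce_size <- function(edges, nodes) {
  best <- 0L
  nn <- length(nodes)
  em <- cbind(match(edges$id1, nodes), match(edges$id2, nodes))
  for (mask in 0:(2^nn - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nn) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- !any(em[, 1] %in% sel & em[, 2] %in% sel)
    if (ok) best <- length(sel)
  }
  best
}

# random kinship graph on n nodes
random_kinship <- function(n, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  sel <- runif(nrow(pairs)) < p_edge
  data.frame(id1 = pairs[sel, 1], id2 = pairs[sel, 2],
             stringsAsFactors = FALSE)
}
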