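test_that("sample gates apply exclusive thresholds", {
  m <- data.frame(
    sample_id = c("A", "B", "C", "D"),
    contamination = c(0.09, 0.08, 0.01, 0.01),
    ccds10x_frac = c(0.95, 0.95, 0.87, 0.88))
  r <- filter_samples(m)
  expect_setequal(r$kept, c("B", "D"))
  expect_equal(r$exclusions$reason[r$exclusions$sample_id == "A"],
               "contamination")
  expect_equal(r$exclusions$reason[r$exclusions$sample_id == "C"],
               "low_ccds_coverage")
  expect_error(filter_samples(rbind(m, m[1, ])), "duplicate")
})

test_that("kinship pruning keeps a maximum unrelated set", {
  m <- data.frame(sample_id = c("A", "B", "C"),
                  contamination = 0, ccds10x_frac = 1)
  kin <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"))
  r <- filter_samples(m, kinship = kin)
  expect_setequal(r$kept, c("A", "C"))  # brute force on the 3-node path

  # random graphs <= 10 nodes: cardinality equals subset-enumeration optimum
  for (s in 1:20) {
    n <- sample(4:10, 1)
    kin <- random_kinship(n, 0.3, seed = s)
    met <- data.frame(sample_id = sprintf("S%02d", 1:n),
                      contamination = 0, ccds10x_frac = 1)
    r <- filter_samples(met, kinship = kin)
    # kept set contains no related pair
    expect_false(any(kin$id1 %in% r$kept & kin$id2 %in% r$kept))
    expect_equal(length(r$kept), mis_bruteforce_size(kin, met$sample_id),
                 info = paste("graph seed", s))
  }
})

test_that("variant QC is an inclusive-boundary conjunction", {
  # every threshold at its inclusive bound still passes
  boundary <- qc_row(qual = 30, qd = 2, gq = 20, read_pos_rank_sum = -3,
                     mq = 40, mq_rank_sum = -9.9, depth = 10, fs = 60,
                     alt_allele_ratio = 0.25)
  expect_true(apply_variant_qc(boundary)$pass)

  # strand-bias cutoff depends on variant type
  expect_true(apply_variant_qc(qc_row(fs = 100, is_indel = TRUE))$pass)
  snv <- apply_variant_qc(qc_row(fs = 100, is_indel = FALSE))
  expect_false(snv$pass)
  expect_match(snv$failed_rules, "fs")

  # het allele balance
  ab <- apply_variant_qc(qc_row(alt_allele_ratio = 0.20))
  expect_false(ab$pass)
  expect_match(ab$failed_rules, "allele_balance")
  # non-het call (no ratio) is exempt from the balance rule
  expect_true(apply_variant_qc(qc_row(alt_allele_ratio = NA))$pass)
  # absent rank sums pass those rules
  expect_true(apply_variant_qc(qc_row(read_pos_rank_sum = NA,
                                      mq_rank_sum = NA))$pass)
  expect_false(apply_variant_qc(qc_row(evs_failure = TRUE))$pass)
  expect_error(apply_variant_qc(qc_row(depth = -1)), "negative depth")
})

test_that("improving any single metric never flips pass to fail", {
  set.seed(21)
  better <- list(qual = 10, qd = 3, gq = 10, read_pos_rank_sum = 2, mq = 10,
                 mq_rank_sum = 3, depth = 10, alt_allele_ratio = 0.2)
  for (i in 1:40) {
    row <- qc_row(qual = runif(1, 0, 60), qd = runif(1, 0, 10),
                  gq = runif(1, 0, 60), read_pos_rank_sum = runif(1, -6, 3),
                  mq = runif(1, 20, 70), mq_rank_sum = runif(1, -15, 3),
                  depth = sample(0:30, 1), fs = runif(1, 0, 250),
                  alt_allele_ratio = runif(1),
                  is_indel = sample(c(TRUE, FALSE), 1),
                  evs_failure = sample(c(TRUE, FALSE), 1))
    base <- apply_variant_qc(row)$pass
    for (f in names(better)) {
      imp <- row
      imp[[f]] <- min(imp[[f]] + better[[f]],
                      if (f == "alt_allele_ratio") 1 else Inf)
      if (base) expect_true(apply_variant_qc(imp)$pass, info = f)
    }
    imp <- row; imp$fs <- max(0, imp$fs - 50)
    if (base) expect_true(apply_variant_qc(imp)$pass, info = "fs")
    imp <- row; imp$evs_failure <- FALSE
    if (base) expect_true(apply_variant_qc(imp)$pass, info = "evs")
  }
})

test_that("coverage independence test matches the exact binomial oracle", {
  # perfect coverage in both cohorts
  expect_equal(coverage_independence_test(849, 849, 15640, 15640), 1)
  # maximal disparity: p effectively zero
  expect_lt(coverage_independence_test(0, 849, 15640, 15640), 1e-100)
  # exact agreement with stats::binom.test under the pooled null
  phat <- (800 + 15000) / (849 + 15640)
  expect_equal(coverage_independence_test(800, 849, 15000, 15640),
               stats::binom.test(800, 849, phat)$p.value, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(50:900, 1); n2 <- sample(100:2000, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next
    ph <- (k1 + k2) / (n1 + n2)
    expect_equal(coverage_independence_test(k1, n1, k2, n2),
                 stats::binom.test(k1, n1, ph)$p.value, tolerance = 1e-10,
                 info = sprintf("k1=%d n1=%d k2=%d n2=%d", k1, n1, k2, n2))
  }
  expect_error(coverage_independence_test(1, 0, 5, 10), "zero-size")
})

test_that("harmonization excludes exactly the imbalanced sites", {
  cfg <- sim_config(n_cases = 849, n_controls = 15640, n_genes = 6,
                    variants_per_gene = 10, seed = 13)
  cs <- simulate_cohort(cfg)
  expect_equal(nrow(harmonize_sites(cs)$excluded), 0)  # fully covered

  # a site covered only in controls is the one excluded
  unc <- Matrix::sparseMatrix(i = which(cs$samples$status == "case"),
                              j = rep(3L, 849), dims = dim(cs$geno))
  cs1 <- callset(cs$samples, cs$variants, Matrix::drop0(cs$geno * 0),
                 uncovered = unc)
  h <- harmonize_sites(cs1)
  expect_equal(h$excluded$variant_id, cs$variants$variant_id[3])

  # sites at coverage (0.5, 1.0): all excluded
  cs2 <- simulate_coverage_imbalance(cs, 20, 0.5, 1.0, seed = 2)
  h2 <- harmonize_sites(cs2)
  expect_true(all(cs$variants$variant_id[1:20] %in% h2$excluded$variant_id))

  # moderate imbalance (0.95, 0.99): per-site decision matches binom.test
  cs3 <- simulate_coverage_imbalance(cs, 15, 0.95, 0.99, seed = 3)
  cc <- covered_counts(cs3)[1:15, ]
  h3 <- harmonize_sites(cs3)
  for (i in 1:15) {
    ph <- (cc$covered_cases[i] + cc$covered_controls[i]) / (849 + 15640)
    p_orc <- stats::binom.test(cc$covered_cases[i], 849, ph)$p.value
    expect_equal(cc$variant_id[i] %in% h3$excluded$variant_id,
                 p_orc <= 0.01, info = paste("site", i))
  }
})

test_that("harmonization under equal coverage is calibrated at alpha", {
  cfg <- sim_config(n_cases = 849, n_controls = 15640, n_genes = 4,
                    variants_per_gene = 100, seed = 17)
  cs <- simulate_cohort(cfg)
  nsite <- nrow(cs$variants)
  cs <- simulate_coverage_imbalance(cs, nsite, 0.9, 0.9, seed = 4)
  h <- harmonize_sites(cs)
  # exact-test discreteness makes the realized rate conservative: it must
  # not exceed the nominal 1% by more than binomial noise
  rate <- nrow(h$excluded) / nsite
  expect_lte(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / nsite))
  # and every decision agrees with the independent oracle
  cc <- covered_counts(cs)
  ph <- (cc$covered_cases + cc$covered_controls) / (849 + 15640)
  orc <- mapply(function(k, p) stats::binom.test(k, 849, p)$p.value,
                cc$covered_cases, ph)
  expect_setequal(h$excluded$variant_id, cc$variant_id[orc <= 0.01])
})
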