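test_that("the exact test reproduces reference tables and degenerate cases", {
  # flagship carrier table: 19/849 cases vs 88/15640 controls
  expect_equal(signif(fisher_two_sided(19, 830, 88, 15552), 3), 2.03e-6)
  expect_equal(fisher_two_sided(0, 849, 0, 15640), 1)
  expect_equal(fisher_two_sided(849, 0, 15640, 0), 1)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_two_sided(1.5, 2, 3, 4), "non-negative")
})

test_that("two-sided p agrees with independent implementations", {
  set.seed(8)
  for (i in 1:60) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    b <- n1 - a; d <- n2 - c
    p <- fisher_two_sided(a, b, c, d)
    expect_equal(p, fet_enum_oracle(a, b, c, d), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(c(a, b, c, d), 2,
                                              byrow = TRUE))$p.value,
                 tolerance = 1e-9,
                 info = sprintf("(%d,%d,%d,%d)", a, b, c, d))
    # label-swap symmetry
    expect_equal(p, fisher_two_sided(c, d, a, b), tolerance = 1e-12)
  }
})

test_that("hypergeometric point masses are normalized and p is tail-monotone", {
  m <- 20; n <- 100; k <- 10
  xs <- max(0, k - n):min(m, k)
  pr <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  mode_x <- xs[which.max(pr)]
  ps <- vapply(xs[xs >= mode_x], function(a)
    fisher_two_sided(a, m - a, k - a, n - k + a), 0)
  expect_true(all(diff(ps) <= 1e-12))  # more extreme table, smaller p
})

test_that("odds ratios match reference estimates and handle zero cells", {
  expect_equal(round(odds_ratio(47, 802, 376, 15264), 2), 2.38)
  expect_equal(round(odds_ratio(51, 798, 404, 15236), 2), 2.41)
  expect_equal(odds_ratio(5, 5, 5, 5), 1)
  expect_equal(odds_ratio(5, 5, 5, 5, method = "cmle"), 1, tolerance = 1e-6)
  # both estimators sit within a cent of 4.04 on the flagship table
  expect_lt(abs(odds_ratio(19, 830, 88, 15552) - 4.04), 0.011)
  expect_lt(abs(odds_ratio(19, 830, 88, 15552, "cmle") - 4.04), 0.011)
  expect_true(is.na(odds_ratio(3, 0, 5, 7)))       # undefined cross-product
  expect_true(is.na(odds_ratio(3, 0, 0, 7, "cmle")))  # infinite CMLE
  expect_error(odds_ratio(1, 2, 3, 4, method = "nope"))
})

test_that("Bonferroni thresholds scale with genes and models", {
  thr <- collapsing_thresholds(18653, 7)
  expect_equal(signif(thr$alpha_genome, 3), 2.68e-6)
  expect_equal(signif(thr$alpha_study, 3), 3.83e-7)
  t1 <- collapsing_thresholds(1, 1)
  expect_equal(c(t1$alpha_genome, t1$alpha_study), c(0.05, 0.05))
  expect_lte(thr$alpha_study, thr$alpha_genome)
  expect_error(collapsing_thresholds(0), ">= 1")
})

test_that("collapsing counts carriers, not alleles, and ranks by p", {
  # one sample with three qualifying variants in a gene contributes 1
  v <- rbind(toy_variant(id = "v1"), toy_variant(id = "v2", af = 0.002),
             toy_variant(id = "v3", af = 0.003))
  v$pos <- c(100L, 200L, 300L)
  cs <- toy_callset(5, 20, v, list(i = c(1, 1, 1), j = c(1, 2, 3),
                                   x = c(1, 1, 1)))
  r <- collapse_and_test(cs, "lof")
  expect_equal(r$case_carriers, 1)
  expect_equal(r$control_carriers, 0)

  # an enriched fixture ranks first and clears genome-wide significance
  cs2 <- make_fixture_from_counts(19, 849, 88, 15640, "KRT82")
  r2 <- collapse_and_test(cs2, "lof", gene_universe = c("AAA", "KRT82", "ZZZ"),
                          thresholds = collapsing_thresholds(18653, 7))
  expect_equal(r2$gene[1], "KRT82")
  expect_true(r2$genome_wide[1])
  expect_false(r2$study_wide[1])
  expect_equal(r2$p_value[2:3], c(1, 1))
  expect_equal(r2$gene[2:3], c("AAA", "ZZZ"))  # p ties break by symbol
})

test_that("per-gene counts equal a brute-force recount on random cohorts", {
  for (s in c(2, 9)) {
    cs <- simulate_cohort(sim_config(n_cases = 40, n_controls = 160,
                                     n_genes = 12, variants_per_gene = 15,
                                     seed = s))
    res <- collapse_and_test(cs, "lof_missense")
    q <- qualifying_variants(cs$variants, "lof_missense")
    G <- as.matrix(cs$geno)
    for (g in unique(cs$variants$gene)) {
      vi <- which(cs$variants$gene == g & q$qualifies)
      carrier <- if (length(vi)) rowSums(G[, vi, drop = FALSE] > 0) > 0 else
        rep(FALSE, nrow(G))
      a <- sum(carrier & cs$samples$status == "case")
      c <- sum(carrier & cs$samples$status == "control")
      row <- res[res$gene == g, ]
      expect_equal(c(row$case_carriers, row$control_carriers), c(a, c),
                   info = paste("gene", g, "seed", s))
    }
  }
})

test_that("recessive collapsing needs hom-alt or two distinct het variants", {
  v <- rbind(toy_variant(id = "v1"), toy_variant(id = "v2", af = 0.002))
  v$pos <- c(100L, 200L)
  # sample 1: two distinct hets (compound het); sample 2: one het;
  # sample 3 (control): hom-alt
  cs <- toy_callset(3, 3, v, list(i = c(1, 1, 2, 4), j = c(1, 2, 1, 2),
                                  x = c(1, 1, 1, 2)))
  r <- collapse_and_test(cs, "recessive")
  expect_equal(r$case_carriers, 1)   # only the compound het
  expect_equal(r$control_carriers, 1)  # the hom-alt
  rd <- collapse_and_test(cs, "lof")
  expect_equal(rd$case_carriers, 2)  # dominant counts any carrier
})

test_that("single-variant tests reuse the exact machinery", {
  expect_equal(signif(carrier_test(15, 849, 72, 15640)$p_value, 3), 3.42e-5)
  expect_equal(round(carrier_test(1, 849, 3, 15640)$p_value, 2), 0.19)
  expect_equal(signif(carrier_test(0, 849, 29, 15640)$p_value, 4), 0.4014)

  cs <- make_fixture_from_counts(3, 30, 2, 100, "G")
  pv <- per_variant_test(cs, "lof")
  expect_equal(nrow(pv), 5)  # one fixture variant per carrier
  expect_true(all(pv$case_carriers + pv$control_carriers == 1))
})

test_that("the full scan pipeline reports per model and harmonizes first", {
  cs <- simulate_cohort(sim_config(
    n_cases = 50, n_controls = 200, n_genes = 10, variants_per_gene = 8,
    enrichments = data.frame(gene = "HIT", case_carrier_freq = 0.5,
                             control_carrier_freq = 0.02, model = "lof"),
    seed = 77))
  scan <- run_burden_scan(cs, models = c("lof", "synonymous_control"))
  expect_named(scan, c("lof", "synonymous_control"))
  expect_equal(scan$lof$gene[1], "HIT")
  expect_true(scan$lof$p_value[1] < 1e-6)
  # the enriched gene carries no synonymous signal
  syn <- scan$synonymous_control
  expect_gt(syn$p_value[syn$gene == "HIT"], 0.05)

  # a harmonization-excluded site cannot contribute qualifying variants
  cs2 <- simulate_coverage_imbalance(
    cs, n_sites = 1, 0, 1, seed = 5,
    sites = cs$variants$variant_id[cs$variants$gene == "HIT"][1])
  scan2 <- run_burden_scan(cs2, models = "lof")
  harm <- attr(scan2, "harmonization")
  expect_true(length(harm$excluded$variant_id) >= 1)
  qs <- qualifying_sets(cs2, "lof", retained = harm$retained)
  expect_false(any(unlist(lapply(qs, `[[`, "variant_id")) %in%
                     harm$excluded$variant_id))
})
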