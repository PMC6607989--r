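test_that("cohort allele counts and MAF match the published conventions", {
  g <- c(rep("het", 20), rep("hom_ref", 100))
  cf <- cohort_frequency(g)
  expect_equal(cf$alt_alleles, 20L)
  expect_equal(cf$n_alleles, 240L)
  expect_equal(round(cf$maf, 4), 0.0833)

  g2 <- c(rep("het", 17), "hom_alt", rep("hom_ref", 102))
  cf2 <- cohort_frequency(g2)
  expect_equal(cf2$alt_alleles, 19L)
  expect_equal(round(cf2$maf, 4), 0.0792)

  expect_equal(cohort_frequency(rep("hom_ref", 120))$alt_alleles, 0L)
  # missing genotypes shrink the denominator
  expect_equal(cohort_frequency(c("het", "missing", "hom_ref"))$n_alleles, 4L)
  expect_error(cohort_frequency(rep("missing", 5)), "all genotypes missing")
})

test_that("fixed-reference z-test matches its closed-form and chi-square oracles", {
  ht <- freq_z_test(5, 100, 0.02)
  expect_equal(unname(ht$statistic), 2.142857, tolerance = 1e-6)
  expect_equal(ht$p.value, 0.0321246, tolerance = 1e-5)
  # z^2 equals the (uncorrected) one-sample goodness-of-fit chi-square
  cs <- suppressWarnings(chisq.test(c(5, 95), p = c(0.02, 0.98),
                                    correct = FALSE))
  expect_equal(unname(ht$statistic)^2, unname(cs$statistic))
  # p_hat == p0 gives z = 0, p = 1
  ht0 <- freq_z_test(12, 240, 0.05)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
})

test_that("p-value decreases strictly with the frequency difference", {
  p <- vapply(12:40, function(x) freq_z_test(x, 240, 0.05)$p.value, numeric(1))
  expect_true(all(diff(p) < 0))  # deviation grows monotonically above 12/240
  # symmetric deviations give identical two-sided p-values
  expect_equal(freq_z_test(6, 240, 0.05)$p.value,
               freq_z_test(18, 240, 0.05)$p.value)
})

test_that("pooled and fixed-reference modes converge for huge panels", {
  fixed <- freq_z_test(5, 100, 0.02)
  pooled <- freq_z_test(5, 100, 0.02, ref_n_alleles = 1e6,
                        config = test_config(variance_mode = "pooled_two_sample"))
  expect_lt(abs(pooled$p.value - fixed$p.value) / fixed$p.value, 0.01)
  expect_error(
    freq_z_test(9, 240, 0.0085,
                config = test_config(variance_mode = "pooled_two_sample")),
    "ref_n_alleles")
  # at moderate panel size the two modes genuinely differ
  pooled214 <- freq_z_test(9, 240, 0.014, ref_n_alleles = 214,
                           config = test_config(variance_mode = "pooled_two_sample"))
  fixed214 <- freq_z_test(9, 240, 0.014)
  expect_gt(pooled214$p.value, fixed214$p.value)
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_equal(bonferroni_threshold(test_config(0.05, 12)), 0.0042)
  expect_equal(bonferroni_threshold(test_config(0.05, 1)), 0.05)
  expect_equal(bonferroni_threshold(test_config(0.01, 4)), 0.0025)
})

test_that("odds ratios match the cross-product and Woolf oracles", {
  expect_equal(odds_ratio(0.0375, 0.0085)$or, 4.5447, tolerance = 1e-4)
  expect_equal(odds_ratio(0.3, 0.3)$or, 1)
  or <- odds_ratio(counts = c(9, 231, 17, 1983))
  # independent cross-product / log-SE computation
  expect_equal(or$or, 9 * 1983 / (231 * 17))
  se <- sqrt(1 / 9 + 1 / 231 + 1 / 17 + 1 / 1983)
  expect_equal(or$ci, exp(log(or$or) + c(-1, 1) * qnorm(0.975) * se))
  expect_false(or$haldane_corrected)
  expect_null(odds_ratio(0.0375, 0.0085)$ci)

  orz <- odds_ratio(counts = c(0, 240, 17, 1983))
  expect_true(orz$haldane_corrected)
  expect_true(is.finite(orz$or) && orz$or > 0)
})

test_that("combination tabulation counts carried variants per patient", {
  t6 <- load_fixture("table6_combinations")
  combos <- combination_table(attr(t6, "genotypes"))
  expect_equal(combos$histogram[["2"]], 17L)
  expect_equal(combos$histogram[["3"]], 5L)
  hom <- combos$homozygous
  expect_setequal(hom$variant, c("IL2RA_rs12722600", "TRAF3_rs138943371"))

  empty <- matrix("hom_ref", 3, 2,
                  dimnames = list(paste0("P", 1:3), c("v1", "v2")))
  expect_equal(length(combination_table(empty)$histogram), 0L)

  one <- matrix("het", 1, 3, dimnames = list("P1", paste0("v", 1:3)))
  expect_equal(combination_table(one)$histogram, c(`3` = 1L))
})

test_that("combination histogram mass equals the carrier-pair count", {
  set.seed(31)
  for (i in 1:5) {
    g <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"), 200,
                       replace = TRUE, prob = c(0.7, 0.2, 0.05, 0.05)),
                20, 10, dimnames = list(paste0("P", 1:20), paste0("v", 1:10)))
    combos <- combination_table(g)
    mass <- sum(as.integer(names(combos$histogram)) * combos$histogram)
    expect_equal(mass, nrow(combos$per_patient))
    expect_equal(mass, sum(g %in% c("het", "hom_alt")))
  }
})

test_that("cohort_assoc tests every variant-panel pair with frequencies", {
  spec <- sim_spec(variant_freqs = c(0.02, 0.01, 0.04), cohort_n = 60,
                   panels = c(panel_a = 500L, panel_b = 214L),
                   panel_missing_prob = 0, seed = 8)
  cohort <- gen_cohort(spec)
  panels <- gen_panels(spec, cohort$variants)
  res <- cohort_assoc(cohort$genotypes, cohort$variants, panels)
  expect_s3_class(res, "assoc_result")
  expect_equal(nrow(res), 3L * 2L)
  tested <- !is.na(res$p_value)
  expect_true(all(res$p_value[tested] >= 0 & res$p_value[tested] <= 1))
  expect_equal(attr(res, "threshold"),
               round(0.05 / attr(res, "n_tests"), 4))
  # cohort_maf always equals the allele ratio
  expect_equal(res$cohort_maf, res$alt_alleles / res$n_alleles)
})
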