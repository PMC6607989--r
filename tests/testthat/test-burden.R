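make_models <- function(lengths) {
  models <- lapply(names(lengths), function(g) {
    list(gene = g, isoforms = list(t1 = list(
      isoform_id = "t1", chrom = "chr1", strand = "+",
      exons = cbind(start = 0L, end = as.integer(lengths[[g]])))))
  })
  names(models) <- names(lengths)
  class(models) <- "gene_models"
  models
}

test_that("longest isoform maximizes exon length with deterministic ties", {
  g <- list(gene = "G", isoforms = list(
    t1 = list(isoform_id = "t1", exons = cbind(start = c(0, 200),
                                               end = c(100, 275))),
    t2 = list(isoform_id = "t2", exons = cbind(start = 0, end = 300))))
  expect_equal(longest_isoform_length(g), 300)
  single <- list(gene = "S", isoforms = list(
    t1 = list(isoform_id = "t1", exons = cbind(start = 0, end = 538))))
  expect_equal(longest_isoform_length(single), 538)
  tie <- list(gene = "T", isoforms = list(
    tB = list(isoform_id = "tB", exons = cbind(start = 0, end = 300)),
    tA = list(isoform_id = "tA", exons = cbind(start = c(0, 150),
                                               end = c(150, 300)))))
  # equal lengths: the lexicographically lowest isoform id wins
  expect_equal(longest_isoform_length(tie), 300)
})

test_that("variant density is count over total longest-isoform length", {
  lengths <- c(g1 = 100, g2 = 100)
  expect_equal(variant_density(c(g1 = 3L, g2 = 0L), lengths, c("g1", "g2")),
               0.015)
  expect_equal(variant_density(integer(), lengths, c("g1", "g2")), 0)
  expect_equal(variant_density(c(g1 = 2L), c(g1 = 538), "g1"), 2 / 538)
  expect_error(variant_density(c(g1 = 1L), c(g1 = 0), "g1"), "zero total")
  expect_error(variant_density(c(g1 = 1L), c(g1 = 10), c("g1", "gX")), "gX")
})

test_that("permutation p matches exhaustive enumeration on a 4-gene universe", {
  lengths <- c(g1 = 100, g2 = 100, g3 = 100, g4 = 100)
  counts <- c(g1 = 3L, g2 = 1L, g3 = 0L, g4 = 2L)
  exact <- enum_perm_p(c("g2", "g3"), lengths, counts, 2)
  expect_equal(exact, 5 / 6)
  res <- permutation_enrichment(c("g2", "g3"), make_models(lengths), counts,
                                perm_config(n_perm = 1000, seed = 1))
  expect_equal(res$observed, 1 / 200)
  sd3 <- 3 * sqrt(exact * (1 - exact) / 1000)
  expect_lt(abs(res$empirical_p - exact), sd3)
})

test_that("all tie rules converge to their enumeration values on random universes", {
  set.seed(99)
  for (rep_i in 1:3) {
    n <- sample(5:7, 1); k <- sample(2:3, 1)
    lengths <- setNames(sample(50:500, n), paste0("g", 1:n))
    counts <- setNames(rpois(n, 1.5), paste0("g", 1:n))
    observed <- sample(names(lengths), k)
    for (rule in c("strictly_greater", "greater_or_equal", "plus_one")) {
      exact <- enum_perm_p(observed, lengths, counts, k, rule)
      target <- enum_mc_target(exact, rule, 2000)
      res <- permutation_enrichment(
        observed, make_models(lengths), counts,
        perm_config(n_perm = 2000, tie_rule = rule, seed = rep_i))
      tol <- 3 * sqrt(max(exact * (1 - exact), 0.25 / 2000) / 2000) + 1e-3
      expect_lt(abs(res$empirical_p - target), tol)
    }
  }
})

test_that("degenerate and extreme observed sets behave per tie rule", {
  lengths <- c(a = 100, b = 100, c = 100)
  # observed set with the unique maximal density
  res <- permutation_enrichment("a", make_models(lengths),
                                c(a = 5L, b = 0L, c = 0L),
                                perm_config(n_perm = 500, seed = 2))
  expect_equal(res$empirical_p, 0)
  # identical counts and lengths everywhere: nothing strictly exceeds
  flat <- permutation_enrichment("a", make_models(lengths),
                                 c(a = 1L, b = 1L, c = 1L),
                                 perm_config(n_perm = 500, seed = 2))
  expect_equal(flat$empirical_p, 0)
  ge <- permutation_enrichment("a", make_models(lengths),
                               c(a = 1L, b = 1L, c = 1L),
                               perm_config(n_perm = 500, seed = 2,
                                           tie_rule = "greater_or_equal"))
  expect_equal(ge$empirical_p, 1)
  expect_error(
    permutation_enrichment("a", make_models(lengths), c(a = 1L),
                           perm_config(set_size = 10)),
    "exceeds")
})

test_that("permutation results are reproducible under a fixed seed", {
  lengths <- setNames(rep(100, 20), paste0("g", 1:20))
  counts <- setNames(rpois(20, 2), paste0("g", 1:20))
  cfg <- perm_config(n_perm = 200, seed = 77)
  r1 <- permutation_enrichment(paste0("g", 1:5), make_models(lengths),
                               counts, cfg)
  r2 <- permutation_enrichment(paste0("g", 1:5), make_models(lengths),
                               counts, cfg)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$empirical_p, r2$empirical_p)
})

test_that("null classification flags stop-gains and frameshifts only", {
  t7 <- load_fixture("table7_c6orf10")
  expect_equal(nrow(t7), 14L)
  expect_equal(sum(classify_null(t7)), 4L)
  expect_false(classify_null("missense"))
  expect_false(classify_null("start_lost"))
  expect_equal(classify_null(c("stop_gained", "frameshift", "synonymous")),
               c(TRUE, TRUE, FALSE))
})

test_that("G-test matches the log-linear deviance oracle", {
  for (tab in list(c(4, 10, 24, 277), c(4, 10, 20, 251), c(7, 3, 12, 41))) {
    ht <- gtest_2x2(tab[1], tab[2], tab[3], tab[4])
    d <- data.frame(y = tab,
                    r = factor(c(1, 1, 2, 2)), c = factor(c(1, 2, 1, 2)))
    dev <- glm(y ~ r + c, family = poisson, data = d)$deviance
    expect_equal(unname(ht$statistic), dev, tolerance = 1e-8)
    expect_equal(ht$p.value, pchisq(dev, 1, lower.tail = FALSE))
  }
  # frozen published-scale values
  expect_equal(unname(gtest_2x2(4, 10, 24, 277)$statistic), 4.7949,
               tolerance = 1e-4)
  expect_equal(gtest_2x2(4, 10, 24, 277)$p.value, 0.02854, tolerance = 1e-3)
  expect_equal(gtest_2x2(4, 10, 20, 251)$p.value, 0.02260, tolerance = 1e-3)
})

test_that("G-test is exact under proportionality and near Pearson when balanced", {
  ht <- gtest_2x2(1, 1, 10, 10)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)
  expect_error(gtest_2x2(0, 0, 5, 5), "degenerate margins")
  set.seed(5)
  for (i in 1:4) {
    tab <- matrix(sample(100:400, 4), 2)
    g <- unname(gtest_2x2(tab)$statistic)
    x2 <- unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic)
    expect_lt(abs(g - x2) / max(x2, 1e-9), 0.02)
  }
})

test_that("zero cells contribute nothing to G (0 log 0 omitted)", {
  ht <- gtest_2x2(0, 10, 5, 5)
  expect_true(is.finite(unname(ht$statistic)))
  expect_true(ht$p.value > 0 && ht$p.value < 1)
})
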