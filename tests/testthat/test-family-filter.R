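test_that("read-fraction calling rule has inclusive boundaries", {
  cfg <- filter_config()
  expect_equal(call_from_reads(30, 20, cfg), "het")     # exactly 40%
  expect_equal(call_from_reads(30, 0, cfg), "hom_ref")
  expect_equal(call_from_reads(2, 38, cfg), "hom_alt")  # 95% >= 0.85
  expect_equal(call_from_reads(15, 85, cfg), "hom_alt") # exactly 85%
  expect_equal(call_from_reads(61, 39, cfg), "hom_ref") # 39% < 40%
  expect_warning(g <- call_from_reads(0, 0, cfg), "zero total")
  expect_equal(g, "missing")
  # other-allele reads count toward the total only
  expect_equal(call_from_reads(10, 10, cfg, other_reads = 20), "hom_ref")
})

test_that("raising the het threshold never enlarges the carrier set", {
  set.seed(7)
  ref <- rpois(300, 40); alt <- rpois(300, 30)
  keep <- ref + alt > 0
  ref <- ref[keep]; alt <- alt[keep]
  prev <- rep(TRUE, length(ref))
  for (thr in c(0.2, 0.3, 0.4, 0.5, 0.6)) {
    cfg <- filter_config(het_fraction_min = thr, hom_alt_fraction_min = 0.95)
    carrier <- call_from_reads(ref, alt, cfg) %in% c("het", "hom_alt")
    expect_true(all(carrier <= prev))
    prev <- carrier
  }
})

test_that("low-frequency filter keeps MAF <= threshold and novel variants", {
  v <- data.frame(
    chrom = "1", pos = 1:4, ref = "A", alt = "G",
    variant_id = c("rs74847855", "rs_common", NA, "rs_intron"),
    gene = c("MALT1", "GENE2", "STAT4", "MALT1"),
    consequence = c("missense", "missense", "synonymous", "intronic"),
    maf_dbsnp150 = c(0.03734, 0.05, NA, 0.001),
    stringsAsFactors = FALSE)
  v$key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  out <- filter_low_frequency(v, c("MALT1", "GENE2", "STAT4"),
                              filter_config())
  expect_setequal(out$gene, c("MALT1", "STAT4"))   # 5% removed, novel kept
  expect_false("intronic" %in% out$consequence)
  # candidate-gene restriction
  out2 <- filter_low_frequency(v, "STAT4", filter_config())
  expect_equal(out2$gene, "STAT4")
  expect_error(filter_low_frequency(v, character(), filter_config()),
               "configuration error")
  # monotonicity in maf_max
  kept1 <- filter_low_frequency(v, v$gene, filter_config(maf_max = 0.02))$key
  kept2 <- filter_low_frequency(v, v$gene, filter_config(maf_max = 0.06))$key
  expect_true(all(kept1 %in% kept2))
})

test_that("segregation assessment matches the published carrier examples", {
  ped <- load_fixture("fig1_pedigree_derived")
  # both carriers affected, parent-child
  s1 <- varsieve:::segregation_from_carriers(c("B-I-2", "B-II-3"), ped)
  expect_true(s1$affected_only)
  expect_true(s1$transmitted)
  # three carriers, no affected parent-child pair
  s2 <- varsieve:::segregation_from_carriers(c("B-I-1", "C-I-1", "C-I-2"), ped)
  expect_false(s2$transmitted)
  expect_false(s2$affected_only)
  expect_equal(s2$n_affected_carriers, 1L)
  # single carrier
  s3 <- varsieve:::segregation_from_carriers("B-I-2", ped)
  expect_false(s3$transmitted)
  expect_true(s3$affected_only)
  # zero carriers: reported, not an error, not affected-only
  s4 <- varsieve:::segregation_from_carriers(character(), ped)
  expect_false(s4$affected_only)
  expect_equal(s4$n_affected_carriers, 0L)
  # carrier outside the pedigree is an error
  expect_error(varsieve:::segregation_from_carriers("Z-9", ped), "Z-9")
})

test_that("segregation agrees with brute force over all carrier pairs", {
  for (seed in 1:6) {
    spec <- sim_spec(n_families = 4, family_offspring = c(3, 2, 2, 1),
                     affected = 0.5, seed = seed)
    fam <- gen_families(spec)
    rep <- segregation_report(fam$variants, fam$genotypes, fam$ped)
    for (i in seq_len(nrow(rep))) {
      carriers <- rep$carriers[[i]]
      expect_equal(rep$transmitted[i], brute_transmitted(carriers, fam$ped))
      expect_equal(rep$affected_only[i], brute_affected_only(carriers, fam$ped))
    }
  }
})

test_that("planted transmission labels are recovered exactly", {
  for (seed in c(3, 19, 101)) {
    fam <- gen_families(sim_spec(seed = seed, affected = 0.6))
    rep <- segregation_report(fam$variants, fam$genotypes, fam$ped)
    expect_equal(rep$transmitted, unname(fam$truth$transmitted))
    for (i in seq_len(nrow(rep))) {
      expect_setequal(rep$carriers[[i]],
                      rownames(fam$genotypes)[fam$truth$carriers[, i]])
    }
  }
})

test_that("candidate selection reproduces the 15-variant screen set", {
  t4 <- load_fixture("table4_family_variants")
  ped <- load_fixture("fig1_pedigree_derived")
  carriers <- setNames(lapply(t4$carriers, as.character), t4$key)
  rep <- segregation_report(t4, pedigree = ped, carriers = carriers)
  expect_equal(nrow(rep), 20L)
  sel <- select_candidates(rep, keep_private_new = TRUE)
  expect_equal(nrow(sel), 15L)
  expect_true("ADAMTS3" %in% sel$gene[sel$novel])
  # the private-new rescue does not pull in the novel UTR variant
  expect_false("RRAS2" %in% sel$gene)
  expect_equal(nrow(select_candidates(rep, keep_private_new = FALSE)), 14L)
})

test_that("an all-unaffected pedigree selects nothing", {
  ped <- load_fixture("fig1_pedigree_derived")
  ped$affected <- FALSE
  t4 <- load_fixture("table4_family_variants")
  carriers <- setNames(lapply(t4$carriers, as.character), t4$key)
  rep <- segregation_report(t4, pedigree = ped, carriers = carriers)
  expect_equal(nrow(select_candidates(rep)), 0L)
})
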