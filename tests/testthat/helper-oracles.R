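# Independent brute-force oracles and tiny in-code fixtures.

# transmission by exhaustive search over all ordered carrier pairs
brute_transmitted <- function(carriers, ped) {
  aff <- ped$id[ped$affected & ped$phenotype_known]
  ac <- intersect(carriers, aff)
  for (p in ac) for (ch in ac) {
    i <- match(ch, ped$id)
    if (identical(ped$father[i], p) || identical(ped$mother[i], p)) return(TRUE)
  }
  FALSE
}

brute_affected_only <- function(carriers, ped) {
  if (!length(carriers)) return(FALSE)
  aff <- ped$id[ped$affected & ped$phenotype_known]
  all(carriers %in% aff)
}

# exact permutation p by enumeration of all k-subsets
enum_perm_p <- function(observed_set, lengths, counts, k,
                        tie_rule = "strictly_greater",
                        statistic = "density") {
  stat <- function(genes) {
    cnt <- counts[genes]
    cnt[is.na(cnt)] <- 0
    if (statistic == "density") sum(cnt) / sum(lengths[genes]) else sum(cnt)
  }
  obs <- stat(observed_set)
  all_stats <- apply(utils::combn(names(lengths), k), 2, stat)
  switch(tie_rule,
         strictly_greater = mean(all_stats > obs),
         greater_or_equal = mean(all_stats >= obs),
         plus_one = mean(all_stats > obs))  # see enum_mc_target
}

# the value a Monte-Carlo estimate with n_perm replicates converges to:
# the plus_one rule adds the finite-sample (r + 1) / (n + 1) shrinkage
enum_mc_target <- function(exact, tie_rule, n_perm) {
  if (tie_rule == "plus_one") (exact * n_perm + 1) / (n_perm + 1) else exact
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

minimal_vcf_header <- function(samples = c("S1", "S2"), ad = TRUE) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MAF_DBSNP150,Number=A,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    if (ad) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# a tiny two-family pedigree built in code
toy_pedigree <- function() {
  ped <- data.frame(
    fam = c("X", "X", "X", "Y", "Y", "Y"),
    id = c("X-I-1", "X-I-2", "X-II-1", "Y-I-1", "Y-I-2", "Y-II-1"),
    father = c(NA, NA, "X-I-1", NA, NA, "Y-I-1"),
    mother = c(NA, NA, "X-I-2", NA, NA, "Y-I-2"),
    sex = c(1L, 2L, 0L, 1L, 2L, 0L),
    affected = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    phenotype_known = TRUE, sequenced = TRUE,
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}
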