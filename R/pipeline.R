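#' Attach reference-panel frequencies to a variant table
#'
#' Adds one `maf_<panel>` column (fractions) per panel, matching variants
#' by `chrom:pos:ref:alt` key. Columns already present (e.g. from VCF
#' INFO) are kept.
#'
#' @param variants Variant data.frame with a `key` column.
#' @param panels A `ref_panels` object.
#' @return The variant data.frame with frequency columns added.
#' @export
attach_panel_freqs <- function(variants, panels) {
  for (p in panels) {
    col <- paste0("maf_", p$name)
    if (!col %in% names(variants)) {
      variants[[col]] <- unname(p$freqs[variants$key])
    }
  }
  variants
}

#' Run the full prioritization pipeline
#'
#' Executes the stages in order: read inputs, candidate-gene and
#' low-frequency filtering, read-fraction genotype calling (when allelic
#' depths are present), segregation assessment, candidate selection,
#' cohort frequency comparison and combination tabulation (when a cohort
#' VCF is given), and the permutation burden test (when gene models are
#' given). Reports are written as TSV with stable column order; the
#' burden result as JSON. A MANIFEST records every stage, the seed and a
#' hash of the configuration; on stage failure the MANIFEST marks the
#' incomplete stage and partial outputs are preserved.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `vcf`, `ped`, `genes` (one symbol per line), `freqs` (panel TSV) --
#'   required; `cohort_vcf`, `gene_models`, `observed_gene_set` --
#'   optional; `outdir` (default `"."`); `filter`, `test`, `perm` --
#'   optional argument lists for [filter_config()], [test_config()],
#'   [perm_config()]; `keep_private_new` (default TRUE); `seed`.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  manifest <- data.frame(stage = character(), status = character(),
                         stringsAsFactors = FALSE)
  note <- function(stage, status) {
    manifest <<- rbind(manifest, data.frame(stage = stage, status = status))
    utils::write.table(
      rbind(manifest,
            data.frame(stage = c("config_hash", "seed"),
                       status = c(cfg_hash, as.character(config$seed %||% NA)))),
      file.path(outdir, "MANIFEST"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  fail <- function(stage, e) {
    note(stage, paste("FAILED:", conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  results <- list()

  tryCatch({
    for (f in c("vcf", "ped", "genes", "freqs")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("required input '", f, "' missing or not found")
      }
    }
    fam <- read_vcf(config$vcf)
    ped <- read_ped(config$ped)
    genes <- readLines(config$genes)
    genes <- trimws(genes[nzchar(trimws(genes)) & !grepl("^#", genes)])
    panels <- read_reference_freqs(config$freqs)
    results$inputs <- list(fam = fam, ped = ped, genes = genes,
                           panels = panels)
    note("read_inputs", "ok")
  }, error = function(e) fail("read_inputs", e))

  tryCatch({
    fcfg <- do.call(filter_config, as.list(config$filter %||% list()))
    fam <- results$inputs$fam
    if (!is.null(fam$alt_reads)) {
      called <- call_from_reads(fam$ref_reads, fam$alt_reads, fcfg,
                                fam$other_reads %||% 0L)
      dim(called) <- dim(fam$genotypes)
      dimnames(called) <- dimnames(fam$genotypes)
      fam$genotypes <- called
    }
    variants <- attach_panel_freqs(fam$variants, results$inputs$panels)
    filtered <- filter_low_frequency(variants, results$inputs$genes, fcfg)
    report <- segregation_report(filtered, fam$genotypes,
                                 results$inputs$ped)
    write_family_report(report, file.path(outdir, "family_report.tsv"))
    selected <- select_candidates(report,
                                  config$keep_private_new %||% TRUE)
    results$family <- list(report = report, selected = selected)
    note("family_filter", "ok")
  }, error = function(e) fail("family_filter", e))

  if (!is.null(config$cohort_vcf)) {
    tryCatch({
      cohort <- read_vcf(config$cohort_vcf)
      keys <- intersect(results$family$selected$key,
                        colnames(cohort$genotypes))
      if (!nrow(cohort$variants) || !length(keys)) {
        warning("cohort VCF empty or no selected variants present; ",
                "association stage skipped")
        note("cohort_assoc", "skipped (empty cohort)")
      } else {
        tcfg <- do.call(test_config, as.list(config$test %||% list()))
        sel <- cohort$variants[cohort$variants$key %in% keys, , drop = FALSE]
        assoc <- cohort_assoc(cohort$genotypes, sel,
                              results$inputs$panels, tcfg)
        utils::write.table(as.data.frame(assoc),
                           file.path(outdir, "association_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        combos <- combination_table(cohort$genotypes[, keys, drop = FALSE])
        utils::write.table(combos$per_patient,
                           file.path(outdir, "combination_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$cohort <- list(assoc = assoc, combos = combos)
        note("cohort_assoc", "ok")
      }
    }, error = function(e) fail("cohort_assoc", e))
  }

  if (!is.null(config$gene_models)) {
    tryCatch({
      models <- read_gene_models(config$gene_models)
      observed <- if (!is.null(config$observed_gene_set)) {
        readLines(config$observed_gene_set)
      } else results$inputs$genes
      observed <- intersect(trimws(observed), names(models))
      counts <- table(results$family$report$gene)
      counts <- stats::setNames(as.integer(counts), names(counts))
      pcfg <- do.call(perm_config, as.list(config$perm %||% list()))
      if (is.null(pcfg$seed)) pcfg$seed <- config$seed
      perm <- permutation_enrichment(observed, models, counts, pcfg)
      jsonlite::write_json(
        list(observed = perm$observed, empirical_p = perm$empirical_p,
             tie_rule = perm$tie_rule, statistic = perm$statistic,
             n_perm = perm$n_perm, set_size = perm$set_size,
             seed = perm$seed,
             null_summary = list(mean = mean(perm$null),
                                 quantiles = stats::quantile(perm$null))),
        file.path(outdir, "burden.json"), auto_unbox = TRUE, digits = NA)
      results$burden <- perm
      note("burden", "ok")
    }, error = function(e) fail("burden", e))
  }

  invisible(results)
}

write_family_report <- function(report, path) {
  out <- as.data.frame(report)
  out$carriers <- vapply(out$carriers, paste, character(1), collapse = "+")
  cols <- intersect(c("gene", "chrom", "pos", "variant_id", "ref", "alt",
                      "consequence", grep("^maf_", names(out), value = TRUE),
                      "carriers", "n_affected_carriers", "affected_only",
                      "transmitted", "novel", "selected"), names(out))
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

# patients carrying exactly k variants, 0 when the bin is empty
hist_count <- function(combos, k) {
  h <- combos$histogram
  if (as.character(k) %in% names(h)) h[[as.character(k)]] else 0L
}

#' Recompute the headline fixture-based results and compare
#'
#' Runs every packaged-fixture check of the pipeline -- segregation
#' counts, frequency-test p-values, Bonferroni threshold, carrier
#' combinations, null-variant classification and odds ratios -- and
#' compares the recomputed values with the published ones.
#'
#' @param only Optional character vector restricting to named checks.
#' @param quiet Suppress printing?
#' @return A data.frame with columns `check`, `expected`, `computed`,
#'   `pass`; attribute `all_pass`.
#' @export
reproduce_paper <- function(only = NULL, quiet = FALSE) {
  t4 <- load_fixture("table4_family_variants")
  ped <- load_fixture("fig1_pedigree_derived")
  carriers <- stats::setNames(lapply(t4$carriers, as.character), t4$key)
  rep4 <- segregation_report(t4, pedigree = ped, carriers = carriers)
  sel <- select_candidates(rep4, keep_private_new = TRUE)

  t5 <- load_fixture("table5_cohort")
  c6 <- t5[t5$gene == "C6orf10", ]
  il <- t5[t5$gene == "IL2RA", ]
  p_c6 <- freq_z_test(c6$ms_alt_alleles, c6$ms_n_alleles,
                      c6$maf_controls_gnomad_nfe)$p.value
  p_il <- freq_z_test(il$ms_alt_alleles, il$ms_n_alleles,
                      il$maf_controls_gnomad_nfe)$p.value
  thr <- bonferroni_threshold(test_config(0.05, n_tests = sum(t5$tested)))
  or_c6 <- odds_ratio(c6$ms_maf, c6$maf_controls_gnomad_nfe)$or
  or_il <- odds_ratio(il$ms_maf, il$maf_controls_gnomad_nfe)$or

  t6 <- load_fixture("table6_combinations")
  combos <- combination_table(attr(t6, "genotypes"))

  t7 <- load_fixture("table7_c6orf10")
  n_null <- sum(classify_null(t7))
  maf_cols <- grep("^maf_", names(t7), value = TRUE)
  n_novel <- sum(apply(is.na(t7[, maf_cols]), 1, all))

  checks <- list(
    list("transmitted_variants", 14, sum(rep4$transmitted), "eq"),
    list("affected_only_variants", 9, sum(rep4$affected_only), "eq"),
    list("selected_candidates", 15, nrow(sel), "eq"),
    list("c6orf10_gnomad_p", 9.89e-07, p_c6, "rel0.01"),
    list("il2ra_gnomad_p_below_1e-20", 1e-20, p_il, "lt"),
    list("bonferroni_threshold", 0.0042, thr, "eq"),
    list("two_variant_carriers", 17, hist_count(combos, 2), "eq"),
    list("three_variant_carriers", 5, hist_count(combos, 3), "eq"),
    list("homozygous_carriages", 2, nrow(combos$homozygous), "eq"),
    list("c6orf10_null_variants", 4, n_null, "eq"),
    list("c6orf10_novel_variants", 10, n_novel, "eq"),
    list("c6orf10_gnomad_or", 4.57, or_c6, "rel0.01"),
    list("il2ra_gnomad_or", 9.88, or_il, "rel0.01")
  )
  out <- do.call(rbind, lapply(checks, function(ck) {
    pass <- switch(ck[[4]],
      eq = isTRUE(all.equal(ck[[2]], unname(ck[[3]]), tolerance = 1e-9)),
      lt = ck[[3]] < ck[[2]],
      rel0.01 = abs(ck[[3]] - ck[[2]]) / ck[[2]] <= 0.01)
    data.frame(check = ck[[1]], expected = ck[[2]], computed = ck[[3]],
               pass = pass, stringsAsFactors = FALSE)
  }))
  if (!is.null(only)) out <- out[out$check %in% only, , drop = FALSE]
  attr(out, "all_pass") <- all(out$pass)
  if (!quiet) {
    print(out, row.names = FALSE, digits = 6)
    cat(if (all(out$pass)) "All checks passed.\n" else
      "SOME CHECKS FAILED.\n")
  }
  invisible(out)
}
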