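#' Configuration for cohort-vs-reference frequency testing
#'
#' @param alpha Family-wise significance level (two-sided). Default 0.05.
#' @param n_tests Bonferroni divisor: the number of variants with a
#'   computable test (not the number screened). Default 1.
#' @param two_sided Two-sided test? Default TRUE.
#' @param variance_mode `"fixed_reference"` (default) treats the reference
#'   MAF as a known population proportion, variance `p0 (1 - p0) / n`;
#'   `"pooled_two_sample"` is the classical pooled-variance two-proportion
#'   z-test and requires the reference allele count.
#' @return A list of class `test_config`.
#' @export
test_config <- function(alpha = 0.05, n_tests = 1L, two_sided = TRUE,
                        variance_mode = c("fixed_reference",
                                          "pooled_two_sample")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 two_sided = two_sided, variance_mode = variance_mode),
            class = "test_config")
}

#' Cohort allele count and frequency at one variant
#'
#' @param genotypes Character vector of genotype calls for one variant
#'   (`hom_ref`, `het`, `hom_alt`, `missing`).
#' @return A list with `alt_alleles` (#het + 2 #hom_alt), `n_alleles`
#'   (2 x non-missing genotypes) and `maf` (their ratio).
#' @export
cohort_frequency <- function(genotypes) {
  ok <- genotypes != "missing" & !is.na(genotypes)
  if (!any(ok)) stop("all genotypes missing: cohort frequency undefined")
  alt <- sum(genotypes[ok] == "het") + 2L * sum(genotypes[ok] == "hom_alt")
  n <- 2L * sum(ok)
  list(alt_alleles = alt, n_alleles = n, maf = alt / n)
}

#' Two-proportion z-test of a cohort frequency against a reference MAF
#'
#' In the default `fixed_reference` mode the reference MAF is treated as a
#' known population proportion: `z = (p_hat - p0) / sqrt(p0 (1 - p0) / n)`.
#' In `pooled_two_sample` mode the classical pooled-variance two-sample
#' statistic is used and `ref_n_alleles` is required. The two converge as
#' the reference panel grows.
#'
#' @param alt_alleles,n_alleles Cohort minor-allele count and total allele
#'   count.
#' @param ref_maf Reference panel MAF (fraction in (0, 1)).
#' @param ref_n_alleles Reference panel allele count (needed for pooled
#'   mode only).
#' @param config A [test_config()].
#' @return An object of class `htest` with the z statistic and p-value.
#' @export
freq_z_test <- function(alt_alleles, n_alleles, ref_maf,
                        ref_n_alleles = NULL, config = test_config()) {
  stopifnot(n_alleles > 0, ref_maf > 0, ref_maf < 1)
  p_hat <- alt_alleles / n_alleles
  if (config$variance_mode == "fixed_reference") {
    se <- sqrt(ref_maf * (1 - ref_maf) / n_alleles)
    method <- "two-proportion z-test (fixed reference variance)"
  } else {
    if (is.null(ref_n_alleles) || is.na(ref_n_alleles)) {
      stop("pooled_two_sample mode requires ref_n_alleles")
    }
    p_pool <- (alt_alleles + ref_maf * ref_n_alleles) /
      (n_alleles + ref_n_alleles)
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n_alleles + 1 / ref_n_alleles))
    method <- "two-proportion z-test (pooled variance)"
  }
  z <- (p_hat - ref_maf) / se
  p <- if (config$two_sided) 2 * stats::pnorm(-abs(z)) else
    stats::pnorm(z, lower.tail = FALSE)
  structure(list(
    statistic = c(z = z),
    p.value = min(p, 1),
    estimate = c(`cohort MAF` = p_hat, `reference MAF` = ref_maf),
    alternative = if (config$two_sided) "two.sided" else "greater",
    method = method,
    data.name = sprintf("%d / %d alleles vs reference MAF %.4g",
                        alt_alleles, n_alleles, ref_maf)
  ), class = "htest")
}

#' Bonferroni-corrected per-test significance threshold
#'
#' `alpha / n_tests`, reported at 4 decimals.
#'
#' @param config A [test_config()].
#' @return The per-test threshold, rounded to 4 decimals.
#' @export
bonferroni_threshold <- function(config = test_config()) {
  round(config$alpha / config$n_tests, 4)
}

#' Allelic odds ratio, with Woolf confidence interval when counts are known
#'
#' From frequencies alone, `OR = [p1/(1-p1)] / [p0/(1-p0)]` and no interval
#' is computed (fabricating one from an assumed panel size would be
#' misleading). With full 2x2 allele counts `c(case_alt, case_ref,
#' ctrl_alt, ctrl_ref)` the Woolf (log) interval
#' `exp(log OR +/- z * sqrt(sum 1/cell))` is added; a zero cell triggers
#' the Haldane-Anscombe 0.5 correction, flagged in the result.
#'
#' @param p1 Cohort (case) MAF, or NULL when `counts` is given.
#' @param p0 Reference MAF, or NULL when `counts` is given.
#' @param counts Optional numeric vector of the four allele counts.
#' @param conf_level Confidence level for the Woolf interval.
#' @return A list of class `odds_ratio`: `or`, `ci` (or NULL),
#'   `haldane_corrected`.
#' @export
odds_ratio <- function(p1 = NULL, p0 = NULL, counts = NULL,
                       conf_level = 0.95) {
  if (!is.null(counts)) {
    stopifnot(length(counts) == 4, all(counts >= 0))
    haldane <- any(counts == 0)
    k <- counts + if (haldane) 0.5 else 0
    or <- (k[1] * k[4]) / (k[2] * k[3])
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(sum(1 / k))
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    stopifnot(p1 > 0, p1 < 1, p0 > 0, p0 < 1)
    or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
    ci <- NULL
    haldane <- FALSE
  }
  structure(list(or = or, ci = ci, conf_level = conf_level,
                 haldane_corrected = haldane),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("Odds ratio: %.3f", x$or))
  if (!is.null(x$ci)) {
    cat(sprintf("  (%d%% CI %.3f-%.3f, Woolf%s)", round(100 * x$conf_level),
                x$ci[1], x$ci[2],
                if (x$haldane_corrected) ", Haldane-Anscombe corrected" else ""))
  }
  cat("\n")
  invisible(x)
}

#' Frequency comparison of cohort variants against all reference panels
#'
#' For each variant with at least one non-missing cohort genotype and each
#' panel with a non-zero frequency entry, computes the cohort MAF, the
#' z-test against the panel MAF, the allelic odds ratio, and nominal /
#' Bonferroni significance flags. `n_tests` defaults to the number of
#' variants with at least one computable test.
#'
#' @param genotypes Sample-by-variant genotype matrix over the screened
#'   variants.
#' @param variants Variant data.frame with a `key` column.
#' @param panels A `ref_panels` object (see [read_reference_freqs()]).
#' @param config A [test_config()]; its `n_tests` is overridden by the
#'   computable-test count unless `fix_n_tests = TRUE`.
#' @param fix_n_tests Keep `config$n_tests` as supplied?
#' @return A data.frame of class `assoc_result`, one row per
#'   variant-panel pair, with attributes `n_tests` and `threshold`.
#' @export
cohort_assoc <- function(genotypes, variants, panels,
                         config = test_config(), fix_n_tests = FALSE) {
  rows <- list()
  testable <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    key <- variants$key[i]
    g <- genotypes[, key]
    if (all(g == "missing")) next
    cf <- cohort_frequency(g)
    for (p in panels) {
      ref <- unname(p$freqs[key])
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, gene = variants$gene[i],
        variant_id = variants$variant_id[i],
        alt_alleles = cf$alt_alleles, n_alleles = cf$n_alleles,
        cohort_maf = cf$maf, panel = p$name, ref_maf = ref %||% NA_real_,
        z = NA_real_, p_value = NA_real_, or = NA_real_,
        stringsAsFactors = FALSE)
      if (is.null(ref) || is.na(ref) || ref <= 0 || ref >= 1) next
      ht <- freq_z_test(cf$alt_alleles, cf$n_alleles, ref,
                        ref_n_alleles = p$n_alleles, config = config)
      r <- rows[[length(rows)]]
      r$z <- unname(ht$statistic)
      r$p_value <- ht$p.value
      r$or <- if (cf$maf > 0 && cf$maf < 1) odds_ratio(cf$maf, ref)$or else
        NA_real_
      rows[[length(rows)]] <- r
      testable[i] <- TRUE
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- if (fix_n_tests) config$n_tests else max(1L, sum(testable))
  thr <- round(config$alpha / n_tests, 4)
  out$significant_nominal <- !is.na(out$p_value) & out$p_value < config$alpha
  out$significant_bonferroni <- !is.na(out$p_value) & out$p_value < thr
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  attr(out, "variance_mode") <- config$variance_mode
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' @export
print.assoc_result <- function(x, digits = 3, ...) {
  cat("Cohort vs reference frequency comparison (", attr(x, "variance_mode"),
      " z-test)\n", sep = "")
  cat("Bonferroni: ", attr(x, "n_tests"), " tests, per-test threshold ",
      format(attr(x, "threshold"), nsmall = 4), "\n", sep = "")
  y <- x
  y$cohort_maf <- sprintf("%.2f%%", 100 * y$cohort_maf)
  y$ref_maf <- ifelse(is.na(y$ref_maf), "-",
                      sprintf("%.2f%%", 100 * y$ref_maf))
  y$p_value <- ifelse(is.na(y$p_value), "-", format(y$p_value, digits = digits))
  print.data.frame(y[, c("gene", "variant_id", "panel", "cohort_maf",
                         "ref_maf", "p_value", "or",
                         "significant_bonferroni")],
                   row.names = FALSE, digits = digits)
  invisible(x)
}

#' Per-patient carried-variant combinations
#'
#' Tabulates, for every patient, the distinct variants carried (with
#' zygosity), the histogram of patients by number of carried variants, and
#' the homozygous carriages.
#'
#' @param genotypes Sample-by-variant genotype matrix over the selected
#'   variants.
#' @param labels Optional named character vector mapping variant keys to
#'   display labels (e.g. `gene rsid`).
#' @return A list of class `carrier_combinations`: `per_patient` (long
#'   data.frame patient/variant/zygosity), `histogram` (named integer
#'   vector: #patients by number of distinct carried variants, k >= 1),
#'   `homozygous` (subset of `per_patient`).
#' @export
combination_table <- function(genotypes, labels = NULL) {
  carried <- genotypes %in% c("het", "hom_alt")
  dim(carried) <- dim(genotypes)
  dimnames(carried) <- dimnames(genotypes)
  idx <- which(carried, arr.ind = TRUE)
  per_patient <- data.frame(
    patient = rownames(genotypes)[idx[, 1]],
    variant = colnames(genotypes)[idx[, 2]],
    zygosity = ifelse(genotypes[idx] == "hom_alt", "hom", "het"),
    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    per_patient$label <- unname(labels[per_patient$variant])
  }
  counts <- table(per_patient$patient)
  histogram <- if (length(counts)) {
    tab <- table(factor(as.integer(counts), levels = seq_len(max(counts))))
    h <- as.integer(tab)
    names(h) <- names(tab)
    h[h > 0]
  } else integer(0)
  structure(list(per_patient = per_patient,
                 histogram = histogram,
                 homozygous = per_patient[per_patient$zygosity == "hom", ,
                                          drop = FALSE]),
            class = "carrier_combinations")
}

#' @export
print.carrier_combinations <- function(x, ...) {
  cat("Carrier combinations:", length(unique(x$per_patient$patient)),
      "carrier patients\n")
  if (length(x$histogram)) {
    for (k in names(x$histogram)) {
      cat(sprintf("  %s patients carry %s variant(s)\n", x$histogram[[k]], k))
    }
  }
  if (nrow(x$homozygous)) {
    cat("Homozygous carriages:\n")
    print.data.frame(x$homozygous, row.names = FALSE)
  }
  invisible(x)
}
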