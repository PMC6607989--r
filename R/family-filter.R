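#' Consequence classes recognized by the pipeline
#'
#' Consequence labels are taken from input annotation (VCF `CSQ_CLASS` or a
#' fixture column); the package never re-annotates from codons.
#'
#' @format Character vector.
#' @export
CONSEQUENCE_CLASSES <- c("missense", "synonymous", "stop_gained",
                         "frameshift", "start_lost", "utr5", "utr3",
                         "intronic", "other")

# consequence classes that alter the protein product
PROTEIN_ALTERING <- c("missense", "stop_gained", "frameshift", "start_lost")

#' Configuration for the family variant filtering cascade
#'
#' @param maf_max Maximum minor allele frequency (fraction) in the primary
#'   reference panel for a variant to count as low-frequency. Default 0.04.
#' @param primary_freq_panel Name of the panel whose MAF the threshold is
#'   applied to (a single panel, not a max over panels: a variant may
#'   exceed `maf_max` in secondary panels and still be kept).
#' @param allowed_consequences Consequence classes kept by the filter;
#'   default is the exonic classes plus UTRs.
#' @param het_fraction_min Minimum alternate-read fraction for a
#'   heterozygous call (inclusive). Default 0.40: a site is called a true
#'   heterozygote when the alternate allele has at least 40% of the total
#'   reads.
#' @param hom_alt_fraction_min Alternate-read fraction at or above which
#'   the call is homozygous alternate (inclusive). Default 0.85.
#' @param require_gene_in_candidates Restrict to the candidate gene list?
#'   Default TRUE.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_max = 0.04,
                          primary_freq_panel = "dbsnp150",
                          allowed_consequences = c("missense", "synonymous",
                                                   "stop_gained", "frameshift",
                                                   "start_lost", "utr5", "utr3"),
                          het_fraction_min = 0.40,
                          hom_alt_fraction_min = 0.85,
                          require_gene_in_candidates = TRUE) {
  stopifnot(maf_max > 0, maf_max < 0.5,
            het_fraction_min > 0,
            het_fraction_min < hom_alt_fraction_min,
            hom_alt_fraction_min <= 1,
            all(allowed_consequences %in% CONSEQUENCE_CLASSES))
  structure(list(maf_max = maf_max,
                 primary_freq_panel = primary_freq_panel,
                 allowed_consequences = allowed_consequences,
                 het_fraction_min = het_fraction_min,
                 hom_alt_fraction_min = hom_alt_fraction_min,
                 require_gene_in_candidates = require_gene_in_candidates),
            class = "filter_config")
}

#' Call a genotype from allelic read counts
#'
#' Implements the read-fraction rule: with `f = alt / total` reads, the
#' call is `hom_ref` when `f` is below `het_fraction_min`, `het` when
#' `het_fraction_min <= f < hom_alt_fraction_min` and `hom_alt` when
#' `f >= hom_alt_fraction_min`. Both boundaries are inclusive on the
#' upper side, so an exact 40% alternate fraction is a heterozygote.
#' Reads supporting other alternate alleles of a split multi-allelic
#' record (`other_reads`) count toward the total but not the alternate.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors of read counts.
#' @param config A [filter_config()].
#' @param other_reads Reads supporting other alleles (default 0).
#' @return Character vector of calls (`hom_ref`, `het`, `hom_alt`,
#'   `missing`). Zero total reads yields `missing` with a warning.
#' @export
call_from_reads <- function(ref_reads, alt_reads, config = filter_config(),
                            other_reads = 0L) {
  stopifnot(all(ref_reads >= 0, na.rm = TRUE),
            all(alt_reads >= 0, na.rm = TRUE))
  total <- ref_reads + alt_reads + other_reads
  f <- alt_reads / total
  out <- ifelse(f >= config$hom_alt_fraction_min, "hom_alt",
         ifelse(f >= config$het_fraction_min, "het", "hom_ref"))
  zero <- !is.na(total) & total == 0
  if (any(zero)) {
    warning(sum(zero), " call(s) with zero total reads set to missing")
    out[zero] <- "missing"
  }
  out[is.na(total)] <- "missing"
  out
}

#' Filter variants to low-frequency candidates
#'
#' Keeps variants whose gene is in the candidate set (when required), whose
#' consequence class is allowed, and whose MAF in the primary panel is at
#' most `maf_max` *or absent* -- novel variants with no reported frequency
#' pass the filter.
#'
#' @param variants Variant data.frame (see [read_vcf()]); the primary
#'   panel MAF is read from the column `maf_<primary_freq_panel>`.
#' @param candidate_genes Character vector of gene symbols.
#' @param config A [filter_config()].
#' @return The filtered variant data.frame.
#' @export
filter_low_frequency <- function(variants, candidate_genes,
                                 config = filter_config()) {
  if (config$require_gene_in_candidates && !length(candidate_genes)) {
    stop("configuration error: empty candidate gene set with ",
         "require_gene_in_candidates = TRUE")
  }
  maf_col <- paste0("maf_", config$primary_freq_panel)
  maf <- if (maf_col %in% names(variants)) variants[[maf_col]] else
    rep(NA_real_, nrow(variants))
  keep <- (is.na(maf) | maf <= config$maf_max) &
    variants$consequence %in% config$allowed_consequences
  if (config$require_gene_in_candidates) {
    keep <- keep & variants$gene %in% candidate_genes
  }
  variants[keep & !is.na(keep), , drop = FALSE]
}

#' Assess segregation of one variant in a pedigree
#'
#' Classifies a variant by its carriers: `affected_only` is TRUE when the
#' variant has at least one carrier and every sequenced carrier is
#' affected; `transmitted` is TRUE when some carrier pair (P, C) exists
#' with P a parent of C and both affected (the parent-child transmission
#' criterion). Missing genotypes are non-carriers.
#'
#' @param variant A variant key (column name of `genotypes`) or a one-row
#'   variant data.frame with a `key` column.
#' @param genotypes Sample-by-variant genotype matrix (values `hom_ref`,
#'   `het`, `hom_alt`, `missing`).
#' @param pedigree A [read_ped()] pedigree containing all carriers.
#' @return A list with `carriers`, `affected_carriers`,
#'   `n_affected_carriers`, `affected_only`, `transmitted`.
#' @export
assess_segregation <- function(variant, genotypes, pedigree) {
  key <- if (is.data.frame(variant)) variant$key[1] else variant
  g <- genotypes[, key]
  carriers <- rownames(genotypes)[g %in% c("het", "hom_alt")]
  segregation_from_carriers(carriers, pedigree)
}

segregation_from_carriers <- function(carriers, pedigree) {
  miss <- setdiff(carriers, pedigree$id)
  if (length(miss)) {
    stop("carrier(s) not in pedigree: ", paste(miss, collapse = ", "))
  }
  idx <- match(carriers, pedigree$id)
  is_aff <- pedigree$affected[idx] & pedigree$phenotype_known[idx]
  affected_carriers <- carriers[is_aff]
  transmitted <- FALSE
  if (length(affected_carriers) >= 2L) {
    ai <- match(affected_carriers, pedigree$id)
    for (ci in ai) {
      parents <- c(pedigree$father[ci], pedigree$mother[ci])
      if (any(!is.na(parents) & parents %in% affected_carriers)) {
        transmitted <- TRUE
        break
      }
    }
  }
  list(carriers = carriers,
       affected_carriers = affected_carriers,
       n_affected_carriers = length(affected_carriers),
       affected_only = length(carriers) > 0L && all(is_aff),
       transmitted = transmitted)
}

#' Segregation report over a filtered variant table
#'
#' Runs [assess_segregation()] for every variant and adds novelty and
#' selection information. A variant is *novel* when it has no non-zero
#' frequency in any reference panel (all `maf_*` columns NA or zero).
#'
#' @param variants Variant data.frame with a `key` column.
#' @param genotypes Sample-by-variant genotype matrix, or `NULL` if
#'   `carriers` is given.
#' @param pedigree A pedigree data.frame.
#' @param carriers Optional named list (by variant key) of carrier ID
#'   vectors, used instead of `genotypes` (e.g. for published carrier
#'   lists).
#' @return A data.frame of class `family_report` with one row per variant:
#'   the variant columns plus `carriers` (list-column),
#'   `n_affected_carriers`, `affected_only`, `transmitted`, `novel`,
#'   `selected` (initialized to `transmitted`; see [select_candidates()]).
#' @export
segregation_report <- function(variants, genotypes = NULL, pedigree,
                               carriers = NULL) {
  if (is.null(carriers)) {
    carriers <- lapply(variants$key, function(k) {
      g <- genotypes[, k]
      rownames(genotypes)[g %in% c("het", "hom_alt")]
    })
    names(carriers) <- variants$key
  }
  seg <- lapply(variants$key, function(k) {
    segregation_from_carriers(carriers[[k]], pedigree)
  })
  maf_cols <- grep("^maf_", names(variants), value = TRUE)
  novel <- if (length(maf_cols)) {
    apply(as.matrix(variants[, maf_cols, drop = FALSE]), 1,
          function(r) all(is.na(r) | r == 0))
  } else rep(TRUE, nrow(variants))
  rep <- variants
  rep$carriers <- I(unname(lapply(seg, `[[`, "carriers")))
  rep$n_affected_carriers <- vapply(seg, `[[`, integer(1), "n_affected_carriers")
  rep$affected_only <- vapply(seg, `[[`, logical(1), "affected_only")
  rep$transmitted <- vapply(seg, `[[`, logical(1), "transmitted")
  rep$novel <- novel
  rep$selected <- rep$transmitted
  class(rep) <- c("family_report", "data.frame")
  rep
}

#' Select candidate variants for cohort screening
#'
#' Returns variants with affected parent-child transmission, plus (when
#' `keep_private_new = TRUE`) novel protein-altering variants absent from
#' all reference panels that are carried by at least one affected member.
#' The protein-altering restriction (missense, stop-gain, frameshift,
#' start-loss) is what rescues a private missense variant while leaving
#' private UTR variants to the transmission criterion alone.
#'
#' @param reports A [segregation_report()] data.frame.
#' @param keep_private_new Rescue private protein-altering variants?
#'   Default TRUE.
#' @return The selected subset, with `selected` set to TRUE.
#' @export
select_candidates <- function(reports, keep_private_new = TRUE) {
  sel <- reports$transmitted
  if (keep_private_new) {
    sel <- sel | (reports$novel &
                    reports$consequence %in% PROTEIN_ALTERING &
                    reports$n_affected_carriers >= 1L)
  }
  out <- reports[sel, , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  out
}

#' @export
print.family_report <- function(x, ...) {
  cat("Family variant report:", nrow(x), "variants;",
      sum(x$transmitted), "with affected parent-child transmission,",
      sum(x$affected_only), "carried only by affected members\n")
  cols <- intersect(c("gene", "chrom", "pos", "variant_id", "consequence",
                      "n_affected_carriers", "affected_only", "transmitted",
                      "novel", "selected"), names(x))
  print.data.frame(x[, cols], row.names = FALSE, ...)
  invisible(x)
}
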