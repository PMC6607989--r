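#' Simulation specification for synthetic pedigree / cohort / panel data
#'
#' Defaults mirror the study scale the pipeline was designed around: three
#' nuclear families (11 genotyped members), a 120-patient unrelated cohort
#' (240 alleles) typed at 15 low-frequency sites, a Tuscany-sized panel of
#' 214 alleles among larger database-style panels, and a gene universe
#' with lognormal exon lengths. Tests use reduced scale through the same
#' interface.
#'
#' @param n_families Number of nuclear families (two founders each).
#' @param family_offspring Integer vector (recycled) of offspring counts
#'   per family.
#' @param affected Either a probability (each member independently
#'   affected) or a character vector of member IDs fixed as affected.
#' @param cohort_n Number of unrelated patients.
#' @param variant_freqs True population MAFs of the simulated sites
#'   (fractions in (0, 0.5]).
#' @param or_inflation Allelic odds ratio by which each variant's cohort
#'   frequency is inflated relative to `variant_freqs` (recycled;
#'   1 = null).
#' @param panels Named integer vector of reference panel allele counts.
#' @param panel_missing_prob Probability that a zero-count panel entry is
#'   rendered absent rather than 0 (emulating dash cells).
#' @param n_genes Universe size.
#' @param n_isoforms Isoforms per gene.
#' @param exon_count_lambda Poisson mean for (exon count - 1).
#' @param exon_len_meanlog,exon_len_sdlog Lognormal exon-length
#'   parameters (bases).
#' @param base_variant_rate Expected low-frequency variants per exonic
#'   base in an unenriched gene (database-scale density).
#' @param enriched_genes Genes whose variant rate is multiplied by
#'   `enrichment_factor`.
#' @param enrichment_factor Density multiplier for enriched genes.
#' @param mean_depth Mean sequencing depth for simulated allelic depths.
#' @param seed Integer seed; every generator is bit-reproducible given the
#'   spec.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_families = 3L,
                     family_offspring = c(2L, 2L, 1L),
                     affected = 0.6,
                     cohort_n = 120L,
                     variant_freqs = c(0.0047, 0.014, 0.028, 0.0047, 0.0421,
                                       0.019, 0.0561, 0.0047, 0.001, 0.0002,
                                       0.0561, 0.0047, 0.014, 0.0094, 0.0047),
                     or_inflation = 1,
                     panels = c(tuscany_1000g = 214L, dbsnp150 = 10000L,
                                exac_nfe = 66000L, controls_gnomad_nfe = 21000L),
                     panel_missing_prob = 0.5,
                     n_genes = 20000L,
                     n_isoforms = 1L,
                     exon_count_lambda = 7,
                     exon_len_meanlog = log(160),
                     exon_len_sdlog = 0.7,
                     base_variant_rate = 0.003,
                     enriched_genes = character(),
                     enrichment_factor = 3,
                     mean_depth = 100,
                     seed = NULL) {
  stopifnot(all(variant_freqs > 0), all(variant_freqs <= 0.5),
            cohort_n > 0, all(panels > 0), n_genes >= 1,
            base_variant_rate > 0, mean_depth > 0)
  structure(as.list(environment()), class = "sim_spec")
}

#' Generate a synthetic gene universe
#'
#' Genes `g00001 ...` are laid out round-robin on 22 autosomes; exon
#' counts are `1 + Poisson(exon_count_lambda)` and exon lengths lognormal,
#' separated by fixed 500-base introns.
#'
#' @param spec A [sim_spec()].
#' @return A `gene_models` object (see [read_gene_models()]).
#' @export
gen_universe <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  chroms <- paste0("chr", rep_len(1:22, n))
  models <- vector("list", n)
  names(models) <- ids
  cursor <- stats::setNames(rep(10000L, 22), paste0("chr", 1:22))
  for (i in seq_len(n)) {
    ch <- chroms[i]
    isoforms <- list()
    for (k in seq_len(spec$n_isoforms)) {
      n_ex <- 1L + stats::rpois(1, spec$exon_count_lambda)
      lens <- as.integer(pmax(1, round(stats::rlnorm(
        n_ex, spec$exon_len_meanlog, spec$exon_len_sdlog))))
      starts <- as.integer(cursor[ch] + cumsum(c(0L, lens[-n_ex] + 500L)))
      iso_id <- paste0("t", k)
      isoforms[[iso_id]] <- list(isoform_id = iso_id, chrom = ch,
                                 strand = "+",
                                 exons = cbind(start = starts,
                                               end = starts + lens))
    }
    span <- max(vapply(isoforms, function(x) max(x$exons[, "end"]),
                       numeric(1)))
    cursor[ch] <- as.integer(span + 5000L)
    models[[i]] <- list(gene = ids[i], isoforms = isoforms)
  }
  class(models) <- "gene_models"
  models
}

#' Generate per-gene low-frequency variant counts with planted enrichment
#'
#' Counts are Poisson with mean `base_variant_rate` x longest-isoform exon
#' length, multiplied by `enrichment_factor` for genes in
#' `enriched_genes`.
#'
#' @param spec A [sim_spec()].
#' @param lengths Named numeric vector of longest-isoform exon lengths
#'   (or a `gene_models` object).
#' @return Named integer vector of variant counts.
#' @export
gen_gene_counts <- function(spec, lengths) {
  if (inherits(lengths, "gene_models")) lengths <- gene_lengths(lengths)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rate <- spec$base_variant_rate * lengths
  rate[names(lengths) %in% spec$enriched_genes] <-
    rate[names(lengths) %in% spec$enriched_genes] * spec$enrichment_factor
  stats::setNames(stats::rpois(length(lengths), rate), names(lengths))
}

sim_variants <- function(spec) {
  n <- length(spec$variant_freqs)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  csq <- sample(c("missense", "synonymous", "utr5", "utr3"), n,
                replace = TRUE, prob = c(0.5, 0.35, 0.05, 0.10))
  v <- data.frame(
    chrom = paste0("chr", rep_len(1:22, n)),
    pos = 1000000L + 1000L * seq_len(n),
    variant_id = ifelse(seq_len(n) %% 5 == 0, NA_character_,
                        sprintf("rs%07d", seq_len(n) * 37L)),
    ref = ref, alt = alt,
    gene = sprintf("gene%02d", seq_len(n)),
    consequence = csq,
    stringsAsFactors = FALSE)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v
}

#' Generate family genotypes with Mendelian transmission and read depths
#'
#' Founder genotypes are binomial at the true MAFs; each offspring
#' receives one allele from each parent. Allelic depths are Poisson with
#' mean `mean_depth`, with alternate fractions centered at 0.5 for
#' heterozygotes and constrained to agree with the read-fraction calling
#' rule. Ground-truth carrier and transmission labels are returned
#' alongside.
#'
#' @param spec A [sim_spec()].
#' @return A list with `variants`, `genotypes`, `ref_reads`, `alt_reads`,
#'   `other_reads`, `ped` (a `pedigree`), and `truth` (list with
#'   `carriers` logical matrix and `transmitted` logical vector).
#' @export
gen_families <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  variants <- sim_variants(spec)
  offspring <- rep_len(spec$family_offspring, spec$n_families)

  ids <- character(); fam <- character(); father <- character()
  mother <- character(); sex <- integer()
  for (f in seq_len(spec$n_families)) {
    fid <- paste0("F", f)
    p1 <- paste0(fid, "-I-1"); p2 <- paste0(fid, "-I-2")
    ids <- c(ids, p1, p2); fam <- c(fam, fid, fid)
    father <- c(father, NA, NA); mother <- c(mother, NA, NA)
    sex <- c(sex, 1L, 2L)
    for (j in seq_len(offspring[f])) {
      ids <- c(ids, paste0(fid, "-II-", j)); fam <- c(fam, fid)
      father <- c(father, p1); mother <- c(mother, p2)
      sex <- c(sex, sample(1:2, 1))
    }
  }
  affected <- if (is.character(spec$affected)) ids %in% spec$affected else
    stats::runif(length(ids)) < spec$affected
  ped <- data.frame(fam = fam, id = ids, father = father, mother = mother,
                    sex = sex, affected = affected,
                    phenotype_known = TRUE, sequenced = TRUE,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")

  n_v <- nrow(variants)
  dose <- matrix(0L, nrow = length(ids), ncol = n_v,
                 dimnames = list(ids, variants$key))
  for (v in seq_len(n_v)) {
    p <- spec$variant_freqs[v]
    for (i in seq_along(ids)) {
      if (is.na(father[i])) {
        dose[i, v] <- stats::rbinom(1, 2, p)
      } else {
        fa <- dose[father[i], v]; mo <- dose[mother[i], v]
        dose[i, v] <- stats::rbinom(1, 1, fa / 2) + stats::rbinom(1, 1, mo / 2)
      }
    }
  }
  genotypes <- matrix(c("hom_ref", "het", "hom_alt")[dose + 1L],
                      nrow = length(ids), dimnames = dimnames(dose))

  cfg <- filter_config()
  depth <- matrix(stats::rpois(length(dose), spec$mean_depth),
                  nrow = length(ids), dimnames = dimnames(dose))
  alt_reads <- matrix(0L, nrow = length(ids), ncol = n_v,
                      dimnames = dimnames(dose))
  for (i in seq_along(dose)) {
    d <- max(depth[i], 1L)
    g <- dose[i]
    target <- c("hom_ref", "het", "hom_alt")[g + 1L]
    for (try in 1:50) {
      a <- switch(target,
                  hom_ref = stats::rbinom(1, d, 0.005),
                  het = stats::rbinom(1, d, 0.5),
                  hom_alt = d - stats::rbinom(1, d, 0.005))
      if (call_from_reads(d - a, a, cfg) == target) break
      a <- switch(target, hom_ref = 0L, het = as.integer(round(d / 2)),
                  hom_alt = d)
    }
    alt_reads[i] <- a
    depth[i] <- d
  }
  ref_reads <- depth - alt_reads

  carriers <- dose > 0L
  transmitted <- vapply(seq_len(n_v), function(v) {
    for (i in seq_along(ids)) {
      if (is.na(father[i]) || !affected[i] || dose[i, v] == 0L) next
      for (par in c(father[i], mother[i])) {
        k <- match(par, ids)
        if (affected[k] && dose[k, v] > 0L) return(TRUE)
      }
    }
    FALSE
  }, logical(1))

  structure(list(variants = variants, genotypes = genotypes,
                 ref_reads = ref_reads, alt_reads = alt_reads,
                 other_reads = matrix(0L, nrow = length(ids), ncol = n_v,
                                      dimnames = dimnames(dose)),
                 ped = ped,
                 truth = list(carriers = carriers, transmitted = transmitted)),
            class = "vcf_data")
}

inflate_freq <- function(p, or) {
  odds <- or * p / (1 - p)
  odds / (1 + odds)
}

#' Generate an unrelated cohort under Hardy-Weinberg genotypes
#'
#' Genotypes are independent across patients and sites; each site's cohort
#' frequency equals the true MAF inflated by the planted allelic odds
#' ratio.
#'
#' @param spec A [sim_spec()].
#' @param variants Optional variant table (defaults to the same synthetic
#'   site set as [gen_families()]).
#' @return A `vcf_data`-shaped list with `variants` and `genotypes`.
#' @export
gen_cohort <- function(spec, variants = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed + 1L)
  if (is.null(variants)) variants <- sim_variants(spec)
  freqs <- inflate_freq(spec$variant_freqs,
                        rep_len(spec$or_inflation, length(spec$variant_freqs)))
  patients <- sprintf("P%03d", seq_len(spec$cohort_n))
  dose <- vapply(freqs, function(p) stats::rbinom(spec$cohort_n, 2, p),
                 integer(spec$cohort_n))
  genotypes <- matrix(c("hom_ref", "het", "hom_alt")[dose + 1L],
                      nrow = spec$cohort_n,
                      dimnames = list(patients, variants$key))
  structure(list(variants = variants, genotypes = genotypes,
                 ref_reads = NULL, alt_reads = NULL, other_reads = NULL),
            class = "vcf_data")
}

#' Generate reference frequency panels by binomial sampling
#'
#' Each panel's MAF at each site is `Binomial(n_alleles, true_freq) /
#' n_alleles`; zero-count entries are rendered absent with probability
#' `panel_missing_prob` (emulating dash cells in printed tables).
#'
#' @param spec A [sim_spec()].
#' @param variants Variant table whose keys index the panel entries
#'   (defaults to the synthetic site set).
#' @param true_freqs True MAFs (defaults to `spec$variant_freqs`).
#' @return A `ref_panels` object.
#' @export
gen_panels <- function(spec, variants = NULL, true_freqs = spec$variant_freqs) {
  if (!is.null(spec$seed)) set.seed(spec$seed + 2L)
  if (is.null(variants)) variants <- sim_variants(spec)
  panels <- lapply(names(spec$panels), function(nm) {
    n <- spec$panels[[nm]]
    counts <- stats::rbinom(length(true_freqs), n, true_freqs)
    keep <- counts > 0 | stats::runif(length(counts)) >= spec$panel_missing_prob
    freqs <- stats::setNames((counts / n)[keep], variants$key[keep])
    list(name = nm, n_alleles = as.integer(n), freqs = freqs)
  })
  names(panels) <- names(spec$panels)
  class(panels) <- "ref_panels"
  panels
}
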