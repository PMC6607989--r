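FIXTURE_NAMES <- c("table4_family_variants", "table5_cohort",
                   "table6_combinations", "table7_c6orf10",
                   "table8_c6orf10_genotypes", "fig1_pedigree_derived")

#' Load a packaged in-study fixture
#'
#' The package ships the published result tables of the motivating study
#' as plain-text fixtures so every pipeline stage can be exercised without
#' downloads. Frequencies are stored exactly as printed (percents) and
#' converted to fractions on load; carrier lists are parsed into
#' list-columns.
#'
#' Available fixtures:
#' \describe{
#'   \item{table4_family_variants}{Family WES variants with per-member
#'     carrier lists (20 records; a published ambiguous duplicate row is
#'     excluded unless `include_ambiguous = TRUE`).}
#'   \item{table5_cohort}{The 15 screened variants with cohort allele
#'     counts, panel MAFs and published p-values; column `tested` marks
#'     the 12 records with a published frequency test.}
#'   \item{table6_combinations}{Cohort patients carrying two or more
#'     screened variants (genotype matrix attached as attribute
#'     `genotypes`).}
#'   \item{table7_c6orf10}{The 14 low-frequency variants from the
#'     C6orf10 3'-exon resequencing, with consequence classes derived
#'     from the amino-acid-change notation.}
#'   \item{table8_c6orf10_genotypes}{Per-patient genotypes of those
#'     variants (long format).}
#'   \item{fig1_pedigree_derived}{The three family pedigrees with the
#'     back-derived affection assignment (flagged via attribute
#'     `provenance`); a reconstruction, not a published table.}
#' }
#'
#' @param name Fixture name.
#' @param include_ambiguous For `table4_family_variants`: keep the
#'   ambiguous duplicate row? Default FALSE.
#' @return A data.frame (or `pedigree`) as described above.
#' @export
load_fixture <- function(name, include_ambiguous = FALSE) {
  if (!name %in% FIXTURE_NAMES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "))
  }
  path <- system.file("extdata", paste0(
    name, if (name == "fig1_pedigree_derived") ".ped" else ".tsv"),
    package = "varsieve", mustWork = TRUE)
  switch(name,
    fig1_pedigree_derived = {
      ped <- read_ped(path)
      attr(ped, "provenance") <-
        "back-derived affection assignment; see package vignette"
      ped
    },
    table4_family_variants = {
      tab <- read_fixture_tsv(path)
      tab <- convert_maf_percent(tab)
      tab$carriers <- I(strsplit(tab$carriers, "+", fixed = TRUE))
      tab$ambiguous <- tab$ambiguous == "TRUE"
      if (!include_ambiguous) tab <- tab[!tab$ambiguous, , drop = FALSE]
      tab$pos <- as.integer(tab$pos)
      tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
      rownames(tab) <- NULL
      tab
    },
    table5_cohort = {
      tab <- read_fixture_tsv(path)
      tab <- convert_maf_percent(tab)
      for (col in c("pos", "ms_alt_alleles", "ms_n_alleles")) {
        tab[[col]] <- as.integer(tab[[col]])
      }
      tab$ms_maf <- as.numeric(tab$ms_maf_pct) / 100
      p_cols <- grep("^p_", names(tab), value = TRUE)
      tab$tested <- apply(tab[, p_cols] != "-", 1, any)
      tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
      attr(tab, "panel_n_alleles") <- read_n_alleles_comments(path)
      tab
    },
    table6_combinations = {
      tab <- read_fixture_tsv(path)
      geno_cols <- setdiff(names(tab),
                           c("patient_id", "sex", "onset_age", "phenotype"))
      g <- as.matrix(tab[, geno_cols])
      g[is.na(g) | g == ""] <- "hom_ref"
      g[g == "het"] <- "het"
      g[g == "hom"] <- "hom_alt"
      rownames(g) <- tab$patient_id
      out <- tab[, c("patient_id", "sex", "onset_age", "phenotype")]
      attr(out, "genotypes") <- g
      out
    },
    table7_c6orf10 = {
      tab <- read_fixture_tsv(path)
      tab <- convert_maf_percent(tab)
      tab$pos <- as.integer(tab$pos)
      tab$ms_alt_alleles <- as.integer(tab$ms_alt_alleles)
      tab$consequence <- consequence_from_aa_change(tab$aa_change)
      tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
      tab
    },
    table8_c6orf10_genotypes = read_fixture_tsv(path)
  )
}

read_fixture_tsv <- function(path) {
  lines <- readLines(path)
  utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, fill = TRUE)
}

read_n_alleles_comments <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE)
  out <- integer()
  for (cm in lines) {
    m <- regmatches(cm, regexec("^#\\s*(\\S+)\\s+n_alleles=(\\d+)", cm))[[1]]
    if (length(m) == 3L) out[m[2]] <- as.integer(m[3])
  }
  out
}

# percent-as-printed maf_* columns -> fractions; "-" (and typographic
# dashes) -> NA
convert_maf_percent <- function(tab) {
  for (col in grep("^maf_", names(tab), value = TRUE)) {
    raw <- trimws(tab[[col]])
    raw[raw %in% c("", "-", "–", "—")] <- NA
    tab[[col]] <- as.numeric(raw) / 100
  }
  tab
}

#' Derive a consequence class from amino-acid-change notation
#'
#' `...stop` is a stop-gain, `...Xfr` a frameshift, an unchanged residue
#' (e.g. `Asp522Asp`) synonymous, `Met1...` a start-loss, anything else
#' missense.
#'
#' @param aa_change Character vector like `"Lys457stop"`, `"Ser454Xfr"`,
#'   `"Asp522Asp"`.
#' @return Character vector of consequence classes.
#' @export
consequence_from_aa_change <- function(aa_change) {
  vapply(aa_change, function(a) {
    if (grepl("stop$", a)) return("stop_gained")
    if (grepl("Xfr$", a)) return("frameshift")
    m <- regmatches(a, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", a))[[1]]
    if (length(m) == 4L) {
      if (m[2] == m[4]) return("synonymous")
      if (m[2] == "Met" && m[3] == "1") return("start_lost")
      return("missense")
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Reference panels derived from a fixture's printed MAF columns
#'
#' Builds a `ref_panels` object from the `maf_*` columns of a loaded
#' fixture table, using the printed frequencies exactly as supplied.
#'
#' @param tab A fixture data.frame with a `key` column and `maf_*`
#'   columns (fractions).
#' @param n_alleles Optional named integer vector of panel allele counts.
#' @return A `ref_panels` object.
#' @export
panels_from_fixture <- function(tab, n_alleles = NULL) {
  if (is.null(n_alleles)) {
    n_alleles <- attr(tab, "panel_n_alleles") %||% integer()
  }
  cols <- grep("^maf_", names(tab), value = TRUE)
  panels <- lapply(cols, function(col) {
    nm <- sub("^maf_", "", col)
    f <- tab[[col]]
    list(name = nm,
         n_alleles = if (nm %in% names(n_alleles)) n_alleles[[nm]] else
           NA_integer_,
         freqs = stats::setNames(f[!is.na(f)], tab$key[!is.na(f)]))
  })
  names(panels) <- sub("^maf_", "", cols)
  class(panels) <- "ref_panels"
  panels
}
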