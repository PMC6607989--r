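#' Read reference-panel allele frequency tables
#'
#' The file is a TSV with key columns `chrom`, `pos`, `ref`, `alt` and one
#' column per reference panel holding minor allele frequencies as
#' *percents* (the way frequency tables are usually printed); they are
#' converted to fractions internally. A dash (`-` or the typographic
#' `–`) or an empty cell means the panel has no entry for that
#' variant. Optional leading comment lines of the form
#' `#<panel> n_alleles=<n>` declare panel allele counts.
#'
#' @param path Path to the TSV file.
#' @return An object of class `ref_panels`: a named list of panels, each a
#'   list with `name`, `n_alleles` (integer or NA when unknown) and
#'   `freqs` (named numeric vector of MAF fractions, names are
#'   `chrom:pos:ref:alt` variant keys).
#' @export
read_reference_freqs <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  n_alleles <- list()
  for (cm in comments) {
    m <- regmatches(cm, regexec("^#\\s*(\\S+)\\s+n_alleles=(\\d+)", cm))[[1]]
    if (length(m) == 3L) n_alleles[[m[2]]] <- as.integer(m[3])
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("frequency table must have columns ", paste(need, collapse = ", "))
  }
  keys <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  panel_cols <- setdiff(names(tab), need)
  panels <- lapply(panel_cols, function(p) {
    raw <- trimws(tab[[p]])
    absent <- raw %in% c("", "-", "–", "—", "NA")
    val <- suppressWarnings(as.numeric(raw))
    if (any(!absent & is.na(val))) {
      stop("non-numeric MAF entry in panel ", p, ": ",
           raw[!absent & is.na(val)][1])
    }
    if (any(!absent & (val < 0 | val > 100))) {
      stop("MAF percent outside [0, 100] in panel ", p)
    }
    freqs <- val[!absent] / 100
    names(freqs) <- keys[!absent]
    list(name = p, n_alleles = n_alleles[[p]] %||% NA_integer_, freqs = freqs)
  })
  names(panels) <- panel_cols
  class(panels) <- "ref_panels"
  panels
}

#' @export
print.ref_panels <- function(x, ...) {
  cat("Reference panels:\n")
  for (p in x) {
    cat(sprintf("  %-24s n_alleles=%-8s entries=%d\n", p$name,
                ifelse(is.na(p$n_alleles), "unknown", p$n_alleles),
                length(p$freqs)))
  }
  invisible(x)
}

#' Write reference panels as a TSV frequency table
#'
#' Inverse of [read_reference_freqs()]: fractions are rendered as percents,
#' absent entries as `-`, panel sizes as `#<panel> n_alleles=<n>` comments.
#'
#' @param panels A `ref_panels` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_freqs <- function(panels, path) {
  keys <- unique(unlist(lapply(panels, function(p) names(p$freqs))))
  parts <- strsplit(keys, ":", fixed = TRUE)
  header <- c(
    vapply(panels[!is.na(vapply(panels, `[[`, NA_integer_, "n_alleles"))],
           function(p) sprintf("#%s n_alleles=%d", p$name, p$n_alleles),
           character(1)),
    paste(c("chrom", "pos", "ref", "alt", names(panels)), collapse = "\t"))
  rows <- vapply(seq_along(keys), function(i) {
    cells <- vapply(panels, function(p) {
      f <- p$freqs[keys[i]]
      if (is.na(f)) "-" else sprintf("%.6g", 100 * f)
    }, character(1))
    paste(c(parts[[i]], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
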