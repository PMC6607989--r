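#' Read a multi-sample VCF into a variant table and genotype matrix
#'
#' Reads a VCF v4.x file (through \pkg{vcfR}) and returns biallelic variant
#' records in file order together with a sample-by-variant genotype matrix.
#' Multi-allelic records are split into one biallelic variant per alternate
#' allele; a sample's genotype for the split variant counts copies of that
#' allele only, while reads supporting other alternate alleles are kept in
#' `other_reads` so they still contribute to the total read depth used by
#' the read-fraction calling rule (see [call_from_reads()]).
#'
#' Recognized optional annotations: the `AD` FORMAT field (allelic depths),
#' and the INFO keys `GENE` (gene symbol), `CSQ_CLASS` (consequence class,
#' one of `r paste(CONSEQUENCE_CLASSES, collapse = ", ")`) and `MAF_<panel>`
#' (per-reference-panel minor allele frequency, as a fraction).
#'
#' @param path Path to an uncompressed VCF file.
#' @return An object of class `vcf_data`: a list with elements
#'   \describe{
#'     \item{variants}{data.frame with columns `chrom`, `pos`, `variant_id`,
#'       `ref`, `alt`, `gene`, `consequence`, `key`, plus one `maf_<panel>`
#'       column per frequency key found (fractions).}
#'     \item{genotypes}{character matrix, samples in rows, variants in
#'       columns (named by variant key), values `hom_ref`, `het`,
#'       `hom_alt` or `missing`.}
#'     \item{ref_reads, alt_reads, other_reads}{integer matrices parallel
#'       to `genotypes`, or `NULL` when the VCF carries no `AD` field.}
#'   }
#' @seealso [write_vcf()] for the inverse operation.
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^##fileformat=VCFv4", first)) {
    stop("malformed VCF header at line 1: expected '##fileformat=VCFv4.x', got '",
         substr(first, 1, 40), "'")
  }
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- x@fix
  if (nrow(fix) == 0L) {
    return(empty_vcf_data())
  }
  n_header <- length(x@meta) + 1L  # meta lines plus the #CHROM line

  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  for (i in seq_along(pos)[-1]) {
    if (chrom[i] == chrom[i - 1L] && pos[i] < pos[i - 1L]) {
      stop("non-monotone position within contig ", chrom[i],
           " at line ", n_header + i)
    }
  }

  has_gt <- ncol(x@gt) > 1L
  samples <- if (has_gt) colnames(x@gt)[-1] else character()
  fmt <- if (has_gt) x@gt[, 1L, drop = TRUE] else character(nrow(fix))
  info <- lapply(fix[, "INFO"], parse_info)

  rows <- list()
  geno <- list()
  adr <- list()
  ada <- list()
  ado <- list()
  has_ad <- FALSE

  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fields <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fields)
    ad_idx <- match("AD", fields)
    cells <- if (has_gt) {
      lapply(x@gt[i, -1, drop = TRUE], function(s) strsplit(s, ":", fixed = TRUE)[[1]])
    } else list()
    gts <- vapply(cells, function(v) if (!is.na(gt_idx) && length(v) >= gt_idx) v[gt_idx] else ".",
                  character(1))
    ads <- lapply(cells, function(v) {
      if (is.na(ad_idx) || length(v) < ad_idx || v[ad_idx] %in% c(".", "")) return(NULL)
      suppressWarnings(as.integer(strsplit(v[ad_idx], ",", fixed = TRUE)[[1]]))
    })

    for (k in seq_along(alts)) {
      inf <- info[[i]]
      row <- list(
        chrom = chrom[i], pos = pos[i],
        variant_id = if (fix[i, "ID"] %in% c(".", NA)) NA_character_ else fix[i, "ID"],
        ref = fix[i, "REF"], alt = alts[k],
        gene = inf[["GENE"]] %||% NA_character_,
        consequence = inf[["CSQ_CLASS"]] %||% NA_character_
      )
      maf_keys <- grep("^MAF_", names(inf), value = TRUE)
      for (m in maf_keys) {
        vals <- suppressWarnings(as.numeric(strsplit(inf[[m]], ",", fixed = TRUE)[[1]]))
        row[[tolower(m)]] <- if (length(vals) >= k) vals[k] else vals[1]
      }
      rows[[length(rows) + 1L]] <- row

      g <- vapply(gts, function(s) gt_from_string(s, k), character(1))
      geno[[length(geno) + 1L]] <- g
      rr <- rep(NA_integer_, length(samples))
      ra <- rep(NA_integer_, length(samples))
      ro <- rep(NA_integer_, length(samples))
      for (j in seq_along(ads)) {
        d <- ads[[j]]
        if (is.null(d) || length(d) < k + 1L) next
        has_ad <- TRUE
        rr[j] <- d[1L]
        ra[j] <- d[k + 1L]
        ro[j] <- sum(d, na.rm = TRUE) - d[1L] - d[k + 1L]
      }
      adr[[length(adr) + 1L]] <- rr
      ada[[length(ada) + 1L]] <- ra
      ado[[length(ado) + 1L]] <- ro
    }
  }

  # unify columns across records (a frequency key may be absent in some rows)
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    miss <- setdiff(all_names, names(r))
    for (m in miss) r[[m]] <- NA_real_
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, rows)
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  rownames(variants) <- NULL

  gmat <- matrix("missing", nrow = length(samples), ncol = nrow(variants),
                 dimnames = list(samples, variants$key))
  for (v in seq_along(geno)) gmat[, v] <- geno[[v]]

  out <- list(variants = variants, genotypes = gmat,
              ref_reads = NULL, alt_reads = NULL, other_reads = NULL)
  if (has_ad) {
    out$ref_reads <- matrix(unlist(adr), nrow = length(samples),
                            dimnames = dimnames(gmat))
    out$alt_reads <- matrix(unlist(ada), nrow = length(samples),
                            dimnames = dimnames(gmat))
    out$other_reads <- matrix(unlist(ado), nrow = length(samples),
                              dimnames = dimnames(gmat))
  }
  class(out) <- "vcf_data"
  out
}

empty_vcf_data <- function() {
  variants <- data.frame(chrom = character(), pos = integer(),
                         variant_id = character(), ref = character(),
                         alt = character(), gene = character(),
                         consequence = character(), key = character(),
                         stringsAsFactors = FALSE)
  structure(list(variants = variants,
                 genotypes = matrix(character(), 0, 0),
                 ref_reads = NULL, alt_reads = NULL, other_reads = NULL),
            class = "vcf_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_info <- function(s) {
  if (is.na(s) || s %in% c(".", "")) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1L) paste(p[-1], collapse = "=") else TRUE)
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  vals
}

gt_from_string <- function(s, alt_index) {
  if (is.na(s) || s %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(s, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(alt_index))
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

#' Write a variant table and genotype matrix as VCF
#'
#' Emits the subset of VCF v4.2 understood by [read_vcf()]: GT (and AD when
#' read counts are present) plus the INFO keys `GENE`, `CSQ_CLASS` and
#' `MAF_<panel>`. Round-trips with [read_vcf()] for biallelic records.
#'
#' @param x A `vcf_data` object (see [read_vcf()]), or any list with the
#'   same `variants`/`genotypes` (and optional read-count) elements.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  has_ad <- !is.null(x$alt_reads)
  samples <- rownames(x$genotypes)
  maf_cols <- grep("^maf_", names(v), value = TRUE)

  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    vapply(maf_cols, function(m) sprintf(
      "##INFO=<ID=%s,Number=A,Type=Float,Description=\"Reference panel MAF (fraction)\">",
      toupper(m)), character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )

  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  recs <- vapply(seq_len(nrow(v)), function(i) {
    info <- character()
    if (!is.na(v$gene[i])) info <- c(info, paste0("GENE=", v$gene[i]))
    if (!is.na(v$consequence[i])) info <- c(info, paste0("CSQ_CLASS=", v$consequence[i]))
    for (m in maf_cols) {
      if (!is.na(v[[m]][i])) info <- c(info, sprintf("%s=%.6g", toupper(m), v[[m]][i]))
    }
    if (!length(info)) info <- "."
    cells <- character()
    if (length(samples)) {
      g <- gt_code[x$genotypes[, i]]
      if (has_ad) {
        ad <- ifelse(is.na(x$ref_reads[, i]) | is.na(x$alt_reads[, i]), ".",
                     paste(x$ref_reads[, i], x$alt_reads[, i], sep = ","))
        cells <- c(if (has_ad) "GT:AD" else "GT", paste(g, ad, sep = ":"))
      } else {
        cells <- c("GT", g)
      }
    }
    paste(c(v$chrom[i], v$pos[i],
            if (is.na(v$variant_id[i])) "." else v$variant_id[i],
            v$ref[i], v$alt[i], ".", "PASS",
            paste(info, collapse = ";"), cells), collapse = "\t")
  }, character(1))

  writeLines(c(meta[nzchar(meta)], recs), path)
  invisible(path)
}
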