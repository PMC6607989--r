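#' Read gene models (isoforms with exon intervals) from BED12 or GTF
#'
#' Parsing goes through \pkg{rtracklayer}; the result is converted to a
#' plain list representation with exon intervals stored 0-based half-open.
#'
#' For BED12 input each line is one isoform; the `name` field uses the
#' convention `GENE|ISOFORM` (a name without `|` yields a single-isoform
#' gene named after itself). For GTF input, `exon` features are grouped by
#' `transcript_id` within `gene_id`.
#'
#' @param path Path to a BED12 or GTF file.
#' @param format `"auto"` (by file extension), `"bed12"` or `"gtf"`.
#' @return An object of class `gene_models`: a named list (one element per
#'   gene symbol), each a list with `gene` and `isoforms`; every isoform is
#'   a list with `isoform_id`, `chrom`, `strand` and `exons` (two-column
#'   matrix of 0-based half-open `[start, end)` intervals, sorted and
#'   non-overlapping).
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed12") "bed" else "gtf"),
    error = function(e) stop("format error reading ", basename(path), ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (format == "bed12") {
    models_from_bed(gr)
  } else {
    models_from_gtf(gr)
  }
}

models_from_bed <- function(gr) {
  out <- list()
  nm <- gr$name
  blocks <- gr$blocks
  for (i in seq_along(gr)) {
    parts <- strsplit(nm[i], "|", fixed = TRUE)[[1]]
    gene <- parts[1]
    iso <- if (length(parts) > 1L) parts[2] else parts[1]
    # blocks are 1-based relative to the range start; convert to genomic 0-based
    offset0 <- GenomicRanges::start(gr)[i] - 1L
    b <- blocks[[i]]
    exons <- cbind(start = offset0 + S4Vectors::start(b) - 1L,
                   end = offset0 + S4Vectors::end(b))
    out <- add_isoform(out, gene, iso,
                       chrom = as.character(GenomicRanges::seqnames(gr))[i],
                       strand = as.character(GenomicRanges::strand(gr))[i],
                       exons = exons)
  }
  finalize_models(out)
}

models_from_gtf <- function(gr) {
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features found in GTF input")
  out <- list()
  gene <- as.character(gr$gene_id)
  iso <- as.character(gr$transcript_id)
  for (key in unique(paste(gene, iso, sep = "\r"))) {
    sel <- paste(gene, iso, sep = "\r") == key
    g <- gr[sel]
    exons <- cbind(start = GenomicRanges::start(g) - 1L,
                   end = GenomicRanges::end(g))
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    out <- add_isoform(out, gene[sel][1], iso[sel][1],
                       chrom = as.character(GenomicRanges::seqnames(g))[1],
                       strand = as.character(GenomicRanges::strand(g))[1],
                       exons = exons)
  }
  finalize_models(out)
}

add_isoform <- function(models, gene, isoform_id, chrom, strand, exons) {
  if (any(exons[, "end"] <= exons[, "start"])) {
    stop("format error: exon with end <= start in isoform ", isoform_id)
  }
  if (nrow(exons) > 1L) {
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    if (any(exons[-1, "start"] < exons[-nrow(exons), "end"])) {
      stop("overlapping exons in isoform ", isoform_id)
    }
  }
  if (is.null(models[[gene]])) models[[gene]] <- list(gene = gene, isoforms = list())
  models[[gene]]$isoforms[[isoform_id]] <- list(
    isoform_id = isoform_id, chrom = chrom, strand = strand, exons = exons)
  models
}

finalize_models <- function(models) {
  models <- lapply(models, function(g) {
    g$isoforms <- g$isoforms[order(names(g$isoforms))]
    g
  })
  class(models) <- "gene_models"
  models
}

#' @export
print.gene_models <- function(x, ...) {
  n_iso <- sum(vapply(x, function(g) length(g$isoforms), integer(1)))
  cat("Gene models:", length(x), "genes,", n_iso, "isoforms\n")
  invisible(x)
}

#' Write gene models as BED12
#'
#' Inverse of [read_gene_models()] for the BED12 representation: one line
#' per isoform, named `GENE|ISOFORM`, exons as blocks.
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  lines <- character()
  for (g in models) {
    for (iso in g$isoforms) {
      ex <- iso$exons
      chrom_start <- ex[1, "start"]
      chrom_end <- ex[nrow(ex), "end"]
      lines <- c(lines, paste(
        iso$chrom, chrom_start, chrom_end,
        paste0(g$gene, "|", iso$isoform_id), 0,
        if (iso$strand %in% c("+", "-")) iso$strand else ".",
        chrom_start, chrom_end, "0,0,0", nrow(ex),
        paste0(paste(ex[, "end"] - ex[, "start"], collapse = ","), ","),
        paste0(paste(ex[, "start"] - chrom_start, collapse = ","), ","),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
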