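#' Read a 6-column PLINK-style pedigree file
#'
#' Columns: family ID, individual ID, father ID, mother ID, sex
#' (1 = male, 2 = female, 0 = unknown) and phenotype (1 = unaffected,
#' 2 = affected, 0 or -9 = unknown). A parent code of `"0"` means no
#' recorded parent. Lines starting with `#` are ignored, so provenance
#' notes can travel with the file.
#'
#' Individuals with unknown phenotype are returned with `affected = FALSE`
#' and `phenotype_known = FALSE`; affected-only logic treats them as
#' non-informative (a variant carried by such an individual is never
#' "present only in affected members").
#'
#' @param path Path to the pedigree file (whitespace- or tab-separated).
#' @return A data.frame of class `pedigree` with columns `fam`, `id`,
#'   `father`, `mother` (NA when absent), `sex`, `affected`,
#'   `phenotype_known`, `sequenced`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_pedigree())
  f <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(f) != 6L)
  if (length(bad)) {
    stop("pedigree line ", bad[1], " has ", lengths(f)[bad[1]],
         " fields; expected 6")
  }
  m <- do.call(rbind, f)
  ped <- data.frame(
    fam = m[, 1], id = m[, 2],
    father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = as.integer(m[, 5]),
    affected = m[, 6] == "2",
    phenotype_known = m[, 6] %in% c("1", "2"),
    sequenced = TRUE,
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

empty_pedigree <- function() {
  ped <- data.frame(fam = character(), id = character(),
                    father = character(), mother = character(),
                    sex = integer(), affected = logical(),
                    phenotype_known = logical(), sequenced = logical(),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    known <- !is.na(ref)
    hit <- match(paste(ped$fam[known], ref[known]), paste(ped$fam, ped$id))
    if (anyNA(hit)) {
      stop("dangling parent ID(s) in pedigree: ",
           paste(unique(ref[known][is.na(hit)]), collapse = ", "))
    }
  }
  # no individual its own ancestor: walk parent links, bounded by pedigree size
  parent_of <- function(id) {
    i <- match(id, ped$id)
    c(ped$father[i], ped$mother[i])
  }
  for (id in ped$id) {
    frontier <- setdiff(parent_of(id), NA)
    for (step in seq_len(nrow(ped))) {
      if (!length(frontier)) break
      if (id %in% frontier) stop("individual ", id, " is its own ancestor")
      frontier <- setdiff(unlist(lapply(frontier, parent_of)), NA)
    }
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals in", length(unique(x$fam)),
      "families;", sum(x$affected), "affected,",
      sum(!x$affected & x$phenotype_known), "unaffected,",
      sum(!x$phenotype_known), "unknown\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a pedigree as a 6-column PED file
#'
#' Inverse of [read_ped()]. Unknown phenotype is written as 0.
#'
#' @param ped A `pedigree` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  pheno <- ifelse(!ped$phenotype_known, 0L, ifelse(ped$affected, 2L, 1L))
  lines <- paste(ped$fam, ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 ped$sex, pheno, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
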