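#' Coordinate conversion between VCF and annotation intervals
#'
#' Variant positions follow the VCF convention (1-based); all annotation
#' intervals in the package are stored 0-based half-open `[start, end)`,
#' as in BED. These two helpers are the single place where the conversion
#' happens.
#'
#' @param pos Integer vector of 1-based VCF positions.
#' @return `pos_to_interval_point()` returns the 0-based point coordinate;
#'   `pos_in_interval()` returns a logical vector.
#' @examples
#' pos_in_interval(100, 99, 100)  # TRUE: last base of [99, 100)
#' pos_in_interval(99, 99, 100)   # FALSE
#' @export
pos_to_interval_point <- function(pos) {
  as.integer(pos) - 1L
}

#' @rdname pos_to_interval_point
#' @param start,end Interval bounds, 0-based half-open.
#' @export
pos_in_interval <- function(pos, start, end) {
  p0 <- pos_to_interval_point(pos)
  p0 >= start & p0 < end
}

# Canonical variant key used to align variant tables, genotype matrices and
# frequency panels.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
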