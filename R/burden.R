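#' Exonic length of the longest isoform of a gene
#'
#' The longest isoform is the one maximizing total exon length; ties are
#' broken deterministically by lowest isoform id (lexicographic).
#'
#' @param gene_model One element of a `gene_models` list (see
#'   [read_gene_models()]).
#' @return Total exon length (bases) of the longest isoform.
#' @export
longest_isoform_length <- function(gene_model) {
  stopifnot(length(gene_model$isoforms) >= 1L)
  lens <- vapply(gene_model$isoforms,
                 function(iso) sum(iso$exons[, "end"] - iso$exons[, "start"]),
                 numeric(1))
  ids <- names(gene_model$isoforms)
  best <- ids[order(-lens, ids)][1]
  unname(lens[best])
}

#' Longest-isoform exonic lengths for a set of gene models
#'
#' @param models A `gene_models` object.
#' @return Named numeric vector of lengths, one per gene.
#' @export
gene_lengths <- function(models) {
  vapply(models, longest_isoform_length, numeric(1))
}

#' Low-frequency variant density of a gene set
#'
#' Total low-frequency variant count over the set divided by the total
#' longest-isoform exon length over the set (variants per base).
#'
#' @param counts Named integer vector: low-frequency variant count per
#'   gene. Genes absent from `counts` count 0.
#' @param lengths Named numeric vector of longest-isoform exon lengths;
#'   must cover every gene in `gene_set`.
#' @param gene_set Character vector of gene symbols.
#' @return Density (variants per base).
#' @export
variant_density <- function(counts, lengths, gene_set) {
  miss <- setdiff(gene_set, names(lengths))
  if (length(miss)) stop("no exon length for gene(s): ",
                         paste(miss, collapse = ", "))
  total_len <- sum(lengths[gene_set])
  if (total_len <= 0) stop("zero total exon length for gene set")
  cnt <- counts[gene_set]
  cnt[is.na(cnt)] <- 0
  sum(cnt) / total_len
}

#' Configuration for the permutation enrichment test
#'
#' @param set_size Number of genes drawn per replicate (the size of the
#'   candidate set; 107 in the motivating design). Defaults to the
#'   observed set size when NULL.
#' @param n_perm Number of permutation replicates. Default 1000.
#' @param tie_rule How the empirical p-value counts replicates:
#'   `"strictly_greater"` (default; the proportion of replicates whose
#'   statistic is strictly higher than the observed value, which can be
#'   exactly 0), `"greater_or_equal"`, or `"plus_one"`
#'   (`(r + 1) / (n + 1)`, never 0).
#' @param exclude_observed_genes Sample null sets from the universe minus
#'   the observed set? Default FALSE (a uniform random sample of the whole
#'   universe).
#' @param statistic `"density"` (variant count normalized by total
#'   longest-isoform exon length; default) or `"count"` (raw variant
#'   count).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(set_size = NULL, n_perm = 1000L,
                        tie_rule = c("strictly_greater", "greater_or_equal",
                                     "plus_one"),
                        exclude_observed_genes = FALSE,
                        statistic = c("density", "count"),
                        seed = NULL) {
  stopifnot(n_perm >= 1)
  structure(list(set_size = set_size, n_perm = as.integer(n_perm),
                 tie_rule = match.arg(tie_rule),
                 exclude_observed_genes = exclude_observed_genes,
                 statistic = match.arg(statistic), seed = seed),
            class = "perm_config")
}

#' Permutation enrichment test of low-frequency variants in a gene set
#'
#' Builds the null distribution of the low-frequency variant density (or
#' raw count) in random gene sets of size `set_size` drawn without
#' replacement from the universe, and returns the empirical p-value: the
#' proportion of replicates whose statistic exceeds the observed one
#' (under the default strict tie rule).
#'
#' @param observed_set Character vector of observed gene symbols (subset
#'   of the universe).
#' @param universe A `gene_models` object, or a named numeric vector of
#'   longest-isoform exon lengths.
#' @param variant_counts Named integer vector of low-frequency variant
#'   counts per gene (genes absent count 0); apply the same MAF/consequence
#'   filter as the family cascade before counting.
#' @param config A [perm_config()].
#' @return An object of class `perm_test`: `observed`, `null`
#'   (length-`n_perm` numeric), `empirical_p`, plus the configuration
#'   used.
#' @export
permutation_enrichment <- function(observed_set, universe, variant_counts,
                                   config = perm_config()) {
  lengths <- if (inherits(universe, "gene_models")) gene_lengths(universe)
             else universe
  miss <- setdiff(observed_set, names(lengths))
  if (length(miss)) stop("observed gene(s) not in universe: ",
                         paste(miss, collapse = ", "))
  set_size <- config$set_size %||% length(observed_set)
  pool <- names(lengths)
  if (config$exclude_observed_genes) pool <- setdiff(pool, observed_set)
  if (set_size > length(pool)) {
    stop("set_size (", set_size, ") exceeds available universe (",
         length(pool), " genes)")
  }
  stat <- function(genes) {
    if (config$statistic == "density") {
      variant_density(variant_counts, lengths, genes)
    } else {
      cnt <- variant_counts[genes]
      sum(cnt, na.rm = TRUE)
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  observed <- stat(observed_set)
  null <- vapply(seq_len(config$n_perm),
                 function(i) stat(sample(pool, set_size)), numeric(1))
  r <- sum(null > observed)
  empirical_p <- switch(config$tie_rule,
    strictly_greater = r / config$n_perm,
    greater_or_equal = sum(null >= observed) / config$n_perm,
    plus_one = (r + 1) / (config$n_perm + 1))
  structure(list(observed = observed, null = null,
                 empirical_p = empirical_p, set_size = set_size,
                 n_perm = config$n_perm, tie_rule = config$tie_rule,
                 statistic = config$statistic, seed = config$seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation enrichment test (", x$statistic, " statistic)\n",
      sep = "")
  cat(sprintf("  observed: %.4g  null mean: %.4g  (%d replicates of %d genes)\n",
              x$observed, mean(x$null), x$n_perm, x$set_size))
  cat(sprintf("  empirical p = %.4g  (tie rule: %s%s)\n", x$empirical_p,
              x$tie_rule,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' @export
plot.perm_test <- function(x, ...) {
  graphics::hist(x$null, breaks = 30, col = "grey85", border = "white",
                 main = "Permutation null distribution",
                 xlab = paste("gene-set", x$statistic), ...)
  graphics::abline(v = x$observed, col = "red3", lwd = 2)
  invisible(x)
}

#' Classify a variant as null (loss of function)
#'
#' A null variant abolishes the protein product: consequence class
#' `stop_gained` (nonsense) or `frameshift`. Start-loss variants are kept
#' with the missense set (they reduce, rather than abolish, the product).
#'
#' @param x A character vector of consequence classes, or a variant
#'   data.frame with a `consequence` column.
#' @return Logical vector.
#' @export
classify_null <- function(x) {
  csq <- if (is.data.frame(x)) x$consequence else x
  csq %in% c("stop_gained", "frameshift")
}

#' Likelihood-ratio (G) test of independence on a 2x2 table
#'
#' `G = 2 sum O log(O / E)` over the four cells, with expected counts from
#' the margins; `0 log 0` terms are omitted. Under independence G is
#' asymptotically chi-square with 1 degree of freedom. Also known as the
#' maximum-likelihood chi-square.
#'
#' @param a,b,c,d The four cell counts (row-wise), or `a` may be a 2x2
#'   matrix.
#' @return An object of class `htest` with `G`, df and p-value.
#' @export
gtest_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  o <- if (is.matrix(a)) as.numeric(t(a)) else c(a, b, c, d)
  stopifnot(length(o) == 4, all(o >= 0))
  m <- matrix(o, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate margins: every row and column sum must be positive")
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  terms <- ifelse(m > 0, m * log(m / e), 0)
  g <- 2 * sum(terms)
  structure(list(
    statistic = c(G = g),
    parameter = c(df = 1),
    p.value = stats::pchisq(g, df = 1, lower.tail = FALSE),
    method = "Likelihood-ratio (G) test of independence, 2x2",
    data.name = paste(o, collapse = ", ")
  ), class = "htest")
}
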