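---
title: "Prioritizing low-frequency variants in candidate genes: methods and design"
author: "varsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing low-frequency variants in candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varsieve)
```

## The problem

Genome-wide association studies of complex diseases such as multiple
sclerosis flag candidate loci through *common* intragenic variants, but a
substantial share of heritability is attributed to *low-frequency*
variants (minor allele frequency, MAF, below a few percent) that
individual association scans are underpowered to detect. A practical
prioritization strategy is to look for low-frequency exonic variants of
GWAS candidate genes that (i) segregate with disease in affected
families, then (ii) show elevated allele frequencies in an unrelated
patient cohort relative to population reference panels. `varsieve`
implements that strategy as a tested, reusable pipeline, together with
the burden statistics used to ask whether the candidate gene set as a
whole is enriched for such variants.

The package operates downstream of read alignment and variant calling:
its inputs are multi-sample variant calls (VCF), a pedigree with
affection status (PED), a candidate gene list, gene/exon annotation
(BED12 or GTF), and reference allele-frequency tables (TSV). Consequence
classes are taken from input annotation and never recomputed from
codons.

## The family filtering cascade

Family calls pass through a cascade of filters:

1. **Candidate-gene restriction** — only variants assigned to the
   candidate list are considered (configurable off).
2. **Low-frequency threshold** — MAF at most `maf_max` (default 0.04)
   in a single designated *primary* panel, or no reported frequency at
   all (novel variants pass). The threshold is deliberately applied to
   one panel, not to the maximum over panels: a variant may legitimately
   sit just above the cutoff in a secondary panel while qualifying in
   the primary one, and a max-over-panels rule would silently change the
   selected set.
3. **Consequence filter** — exonic classes plus UTRs by default.
4. **Read-fraction genotype calling** — where allelic depths are
   available, a call with alternate fraction `f = alt / total` is a true
   heterozygote when `f >= 0.40` (inclusive), homozygous-alternate when
   `f >= 0.85`, and homozygous-reference otherwise. The 0.40 het bound
   is the conventional verification threshold for this design; the 0.85
   hom-alt bound is this package's choice (only the het lower bound is
   conventionally fixed) and both are configurable. Reads supporting
   other alternate alleles of a split multi-allelic record count toward
   the total but not the alternate.
5. **Segregation** — per variant, the carriers (het or hom-alt) are
   classified: *affected-only* when every sequenced carrier is affected,
   and *transmitted* when a carrier pair (parent, child) exists with
   both affected. Individuals with unknown phenotype are treated as
   unaffected for both criteria. Zero-carrier variants are reported and
   flagged, never an error.

The MAF filter runs before the carrier criteria; the order does not
change the final set, and filtering first keeps the segregation step
cheap.

`select_candidates()` returns the transmitted variants plus, when
`keep_private_new = TRUE`, *private* protein-altering variants: novel
variants (no non-zero frequency in any panel) carried by at least one
affected member with a missense, stop-gain, frameshift or start-loss
consequence. The protein-altering restriction is a deliberate design
choice: an unvalidated private variant is only worth carrying into a
cohort screen when it plausibly changes the protein, whereas a private
UTR variant has to earn its place through the transmission criterion.
On the packaged family fixture this rescues exactly one private
missense variant alongside the 14 transmitted ones.

## Frequency comparison against reference panels

For each screened variant the cohort MAF is `p̂ = x / n` with
`x = #het + 2·#hom-alt` and `n = 2 ×` (non-missing genotypes). The
default test against a panel frequency `p₀` is the **fixed-reference
z-test**

$$ z = \frac{\hat p - p_0}{\sqrt{p_0 (1 - p_0) / n}}, $$

which treats the panel MAF as a known population proportion — the
appropriate model when the panel is orders of magnitude larger than the
cohort (dbSNP, ExAC, gnomAD) and the only form whose p-values track the
published analyses this pipeline emulates. The classical
pooled-variance two-proportion z-test is available as
`variance_mode = "pooled_two_sample"` and requires the panel allele
count; the two converge as the panel grows. For a small panel (say
a few hundred alleles) the pooled test is markedly more conservative —
with such panels the reported "fixed reference" p-values understate the
uncertainty in `p₀`, which is why reports always name the variance mode
used. The normal approximation is anti-conservative for very small
`p₀ n` (expected allele counts below ~1); the type-I calibration
property in the test suite is therefore asserted at `p₀ ≥ 0.05`.

Multiple testing uses the Bonferroni rule `alpha / n_tests`, where
`n_tests` defaults to the number of variants with at least one
computable test (a panel frequency strictly between 0 and 1), not the
number screened.

Odds ratios use the allelic cross-product
`OR = [p̂/(1−p̂)] / [p₀/(1−p₀)]`. A 95% interval is computed only when
full 2×2 allele counts are available (Woolf's log interval,
`exp(ln OR ± 1.96 √Σ 1/cell)`, with the Haldane–Anscombe 0.5 correction
and a flag when a cell is zero); with frequency-only panels the CI is
omitted rather than fabricated from an assumed panel size.

## Carrier combinations

`combination_table()` tabulates, per patient, the distinct screened
variants carried (with zygosity), and the histogram of patients by
number of carried variants. The histogram mass identity
`Σ k · count(k) = #(patient, variant) carrier pairs` is enforced as a
test invariant.

## Burden statistics

**Permutation enrichment.** To ask whether an observed candidate set is
enriched for low-frequency variants, the null distribution is built by
drawing random gene sets of the same size (without replacement, uniform
over the annotation universe) and computing for each the
*exon-length-normalized density*: the total low-frequency variant count
divided by the total exonic length of each gene's longest isoform
(ties between isoforms break to the lexicographically lowest
identifier). The empirical p-value is the proportion of replicates
whose statistic is *strictly higher* than the observed one — the
literal published rule, kept as the default `tie_rule` even though it
can return exactly 0; `plus_one` (`(r+1)/(n+1)`, never 0) and
`greater_or_equal` are offered, and every report names the rule used.
The raw (unnormalized) variant count is available via
`statistic = "count"` since the published description is ambiguous
between the two; density is primary because it is the form that
actually corrects for gene length. Whether the observed genes are
excluded from the sampling universe is also configurable
(`exclude_observed_genes`, default off: a uniform random sample of the
whole universe, as literally described). Replicates are independent;
results are bit-reproducible under a fixed seed.

**Null-variant proportion.** A variant is *null* (loss of function)
when its consequence is stop-gain or frameshift; start-loss variants
are counted with the missense set, since they reduce rather than
abolish the product. Proportions of null variants between a cohort and
a database are compared with the likelihood-ratio (G) test on the 2×2
table, `G = 2 Σ O ln(O/E)` with 1 df and `0·ln 0` terms omitted — the
"maximum-likelihood chi-square". Note that plain G-tests on the
published 2×2 counts of the motivating study give p ≈ 0.029 and
≈ 0.023 rather than the published 0.0254/0.0184; the exact published
variant (software or corrections) is unstated, so the package
implements the standard G-test and the test suite freezes the
standard-G values (cross-checked against the Poisson log-linear
deviance).

## The synthetic-data module

`sim_spec()` + `gen_*()` generate inputs with the statistical structure
the analysis assumes, at the study's scale by default: three nuclear
families (11 genotyped members), a 120-patient cohort (240 alleles)
typed at 15 low-frequency sites, a 214-allele Tuscany-style panel among
larger database-style panels, and a gene universe with
`1 + Poisson(7)` exons per gene and lognormal exon lengths (median
160 bp). Specifically:

- **Families**: founder genotypes binomial at the true MAFs; offspring
  by Mendelian transmission; allelic depths Poisson (mean 100) with het
  alternate fractions centered at 0.5 and constrained to agree with the
  calling rule; ground-truth carrier and transmission labels emitted
  alongside (the oracle for the segregation tests).
- **Cohort**: Hardy–Weinberg genotypes, independent across patients and
  sites; planted signals inflate a site's frequency by a stated allelic
  odds ratio.
- **Panels**: binomial sampling at each panel's allele count;
  zero-count entries rendered absent with configurable probability, to
  emulate dash cells in printed tables.
- **Gene counts**: per-gene low-frequency variant counts Poisson with
  mean `base_variant_rate × length`, default 0.003 variants per exonic
  base — the density scale seen in population databases over a
  well-covered locus — multiplied by `enrichment_factor` for planted
  genes.

What the generator does *not* emulate: linkage disequilibrium between
sites (all sites independent), population structure, and
sequencing-error or mapping artifacts. Passing the recovery and
calibration tests therefore shows the statistics behave correctly under
the model's own assumptions, not that those assumptions hold in any
particular real data set — in real cohorts, LD between screened
variants would make the combination counts non-independent, and panel
mismatch (ancestry) can inflate every frequency test at once.

## Numerical choices and degenerate inputs

- Frequencies are fractions internally and 2-decimal percents in
  rendered reports; fixture frequencies are stored exactly as printed
  and converted once on load, never re-rounded.
- Coordinates: VCF positions are 1-based, annotation intervals 0-based
  half-open; the conversion lives in one audited helper
  (`pos_in_interval()`), so a variant at position `p` falls in exon
  `[s, e)` iff `s < p ≤ e`.
- Boundary calls at exactly 40% / 85% alternate reads are het /
  hom-alt respectively (inclusive upper rules).
- Zero read depth yields a missing genotype with a warning, not an
  error; all-missing cohort genotypes at a variant are an error.
- Degenerate G-test margins (an empty row or column) are an error;
  zero cells inside a non-degenerate table contribute nothing to G.
- The derived family affection labels ship as a separate, clearly
  flagged fixture (`fig1_pedigree_derived`) rather than being merged
  into any parser: they are a reconstruction — the unique assignment
  consistent with all published constraints, verified by brute force —
  not published data.

## Problem sizes in the test suite

The packaged tests run the statistics at desk scale: exhaustive
enumeration oracles on universes of up to ~130 subsets, 500-replicate
uniformity and odds-ratio-recovery simulations, a 2000-replicate
type-I calibration, and 100-replicate planted-enrichment recovery on a
300-gene universe. These sizes were chosen so the full suite completes
in well under a minute while keeping Monte-Carlo assertion bounds
(three binomial standard deviations) meaningful.

## Known limitations

- The package does not compute linkage/LOD scores, de novo detection,
  X-linked or imprinting models, genotype likelihoods, SKAT/CMC-style
  weighted aggregation, or covariate-adjusted association.
- The fixed-reference z-test inherits the normal approximation's
  anti-conservatism at very small expected counts; exact binomial
  alternatives are deliberately left to the user (they are used only as
  oracles in the test suite).
- Odds-ratio confidence intervals require allele counts; published
  intervals computed from undisclosed reference counts cannot be
  reproduced exactly from frequencies alone.
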