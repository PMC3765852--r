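---
title: "Methods: tag-based digital gene expression profiling with tagdge"
author: "tagdge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Tag-based digital gene expression (DGE) counts short 3' sequence tags rather
than whole reads. In the wet protocol, NlaIII cuts cDNA at every CATG; the
3'-most fragment stays bead-bound, and MmeI releases a 17-bp fragment
downstream of the CATG, so each transcript contributes one species of 21-nt
tag (CATG + 17 nt). Expression is the number of times that tag is sequenced.
`tagdge` implements the informatic side of this design end to end:

1. **Virtual reference library** (`build_virtual_library`): every CATG on the
   sense strand of every reference gene with at least 17 nt downstream yields
   an indexed CATG+17 tag. All sites are indexed — not only the 3'-most one —
   so that tags from partial digestion or internal sites still resolve;
   the 3'-most ("canonical") tag per gene is tracked separately because it is
   what the simulator emits and what the protocol predominantly produces.
   Windows containing N are skipped and counted. Reverse-complement indexing
   exists behind `both_strands = TRUE` but is off by default: the protocol
   sequences the mRNA strand.
2. **QC** (`clean_tags`): reads of the wrong length, reads containing N,
   non-nucleotide impurities, and adaptor-prefix matches are removed;
   survivors aggregate to distinct (tag, count) pairs. Copy-number-1 removal
   is available (`drop_singletons`) but off by default — it is a protocol
   variant, not a requirement.
3. **Mapping** (`map_tags`): at most one mismatch, with *exact-match
   priority*: a tag with an exact hit is resolved at distance 0 only;
   otherwise all distance-1 hits are pooled. Without this priority every
   exact hit would accrete spurious 1-mismatch co-hits and the unambiguous
   class would collapse. Ambiguity is decided at the *gene* level: a tag
   hitting two sites of one gene is unambiguous for that gene; a tag whose
   resolved hit set touches two genes is ambiguous and excluded from
   expression counting; a tag with no hit is unknown. Mismatches are allowed
   anywhere in the 21-mer including the CATG anchor (sequencing errors do not
   respect enzyme biology); `anchor_exact = TRUE` restricts them to the 17-nt
   variable region.
4. **Quantification** (`to_tpm`): TPM here is *tag copies per million clean
   tags* — pure library-size normalization. Tag counts are insensitive to
   gene length by design (one tag species per transcript), so no length
   correction applies.
5. **Differential expression** (`call_degs`): the Audic–Claverie exact test
   on raw counts, BH FDR, and the thresholds FDR ≤ 0.001 with
   |log2 ratio| ≥ 1.
6. **Diagnostics**: tag-abundance distributions, gene-detection saturation
   curves under seeded subsampling, and Pearson correlation between
   libraries over the union of distinct tags (absent entities at 0,
   untransformed TPM by default, `log = TRUE` available — publications vary
   and rarely say which they used).
7. **Downstream** (`hypergeom_enrich`, `ddct`): upper-tail hypergeometric
   term enrichment of gene sets against a background universe, and
   delta-delta-Ct qPCR summaries.

## The Audic–Claverie test

For a gene seen `x` times among `N1` clean tags in one library, the
probability of seeing it `y` times among `N2` in the other, under equal
underlying expression, is

$$ p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
   \frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}} $$

a negative-binomial-shaped kernel in the depth ratio \(r = N_2/N_1\). All
evaluation is in log space via `lgamma`, so counts up to \(10^7\) neither
overflow nor lose the tails; tail sums use chunked log-sum-exp, and the
upper (infinite) tail is summed forward until it has passed the kernel mode
and the running chunk falls 40 log-units below the accumulated mass.

**Two-sidedness.** The natural "double the smaller tail" construction on one
orientation (tails of \(y\) given \(x\)) is *not* invariant to swapping the
two libraries: the swapped lower tail equals the original upper tail minus
the observed point mass, a discrepancy that is far from negligible at small
counts. Since a two-sample test should not depend on which sample is listed
first, `ac_pvalue` evaluates the inclusive tails in *both* orientations
(\(y\mid x\) at ratio \(r\) and \(x \mid y\) at ratio \(1/r\)) and doubles
the smallest of the four sums, capped at 1. This is exactly symmetric by
construction, still yields \(p = 1\) at the equal-count equal-depth center,
and is at most one point mass smaller than either one-orientation doubled
tail. The test suite checks it against an independent route through
`pnbinom` (the kernel is NB with size \(x+1\) and success probability
\(N_1/(N_1+N_2)\)) and verifies conservative type-I behavior on simulated
null genes.

**FDR.** The multiple-testing correction is Benjamini–Hochberg step-up
(`p.adjust`), the standard realization of "expected V/R below a cutoff".
Genes with zero counts in both libraries are excluded from testing so they
do not inflate the BH denominator.

**Zero substitution.** The log2 ratio is computed on TPM with 0 replaced by
0.001 TPM, so genes expressed in only one sample get a large finite fold
change instead of ±Inf. The substitution affects the ratio *only*; p-values
always use raw counts.

## The synthetic-data generator

Downstream correctness is demonstrated on generated data with known truth
(`synthetic_config`, `generate_transcriptome`, `make_de_experiment`).
Defaults describe a small but realistic tag-profiling study:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 200 | large enough for FDR behavior, small enough for fast tests |
| `length_min/max` | 200–2000 nt | spans the short-unigene range of de novo assemblies (mean ~500 nt) |
| `gc_fraction` | 0.45 | typical plant transcriptome GC |
| `expression_shape` | 1.5 (log-normal sigma) | heavy tail: a small subset of mRNAs carries most tag mass |
| `depth` | 5×10^5 | per-library tag count keeping count statistics realistic at 200 genes |
| `error_rate` | 0.001/base | Illumina-era substitution error |
| `junk_fraction` | 0.05 | N-containing and adaptor reads that QC must remove |
| `de_fraction`, `de_log2fc` | 0.1, 2 | planted signal: 10% of genes at 4-fold, balanced up/down |
| `catg_fraction` | 0.95 | a 5% holdout without any CATG exercises the "genes with CATG sites" accounting |

The simulator emits only the 3'-most eligible tag per transcript (the
fragment the enzyme chemistry retains), while the virtual library indexes
*all* sites; that deliberate asymmetry mirrors the real pipeline and lets
tests exercise multi-site genes. Reads are emitted exactly `depth` at a
time; junk reads are split between N-containing 21-mers and an adaptor
sequence. Every generator is a pure function of (config, seed): the caller's
RNG state is saved and restored.

What the generator does **not** emulate: MmeI cut-site jitter, PCR
duplication bias, quality-score structure, paired ends, incomplete
digestion, or cross-gene sequence homology beyond chance 1-mismatch
collisions. Passing recovery tests therefore demonstrates the pipeline's
arithmetic and logic, not robustness to those real-data pathologies.

## Numerical and formatting choices

- Table percentages round *half away from zero* to two decimals
  (`mapping_percent`); base `round()` is half-even and does not reproduce
  printed summary tables.
- The 1-mismatch index path enumerates the 63 single-substitution variants
  of each unmatched tag against a hash of reference tags (sublinear in
  reference size); `method = "brute"` computes all-pairs Hamming distances
  in C++ and is required by the tests to agree exactly.
- Saturation subsamples are nested prefixes of one seeded permutation of tag
  copies, making the detected-gene series non-decreasing by construction.
- p-values below the double-precision minimum underflow to exactly 0; they
  are reported as 0 rather than clamped to a fake epsilon.
- Delta-delta-Ct averages technical replicates within each biological
  replicate, differences target minus reference per replicate, then averages
  biological replicates (matching a 5 biological × 3 technical design); a
  pooled mode exists behind `pooled = TRUE`. The across-biological-replicate
  SD of per-replicate relative expression is reported.

## Problem sizes used by the test suite

Unit tests run on references of 10–300 genes and libraries of 10^2–3×10^5
tags. The acceptance-style suites use: 1,000 random count pairs against the
p-value oracle; 5,000 null genes at depth 10^6 for type-I error; ten
200-gene, 5×10^5-tag experiments for planted-DE recovery; one hundred
200-gene references × ~10^4 tags for index-vs-brute mapping equivalence.
These sizes were chosen so the full suite completes in minutes while keeping
every statistical check adequately powered.

## Known limitations

- Reference redundancy removal (merging unigenes/ESTs/records into a
  non-redundant gene set) is out of scope; duplicate sequences under
  different ids are tolerated and surface as shared tags.
- Only substitution mismatches are modeled (no indels) — appropriate for
  fixed-length tag matching.
- The enrichment module does no GO-graph propagation; annotations are taken
  as given.
- Mapping with `max_mismatch > 1` is deliberately unsupported; the tag is
  too short for 2-mismatch specificity.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_genes = 200, depth = 5e5, error_rate = 0, seed = 1)
exp <- make_de_experiment(cfg)
ref <- build_virtual_library(exp$reference)
lib_a <- clean_tags(exp$library_a, "CK")
lib_b <- clean_tags(exp$library_b, "JA")
prof_a <- to_tpm(map_tags(lib_a, ref), gene_universe = ref$gene_ids)
prof_b <- to_tpm(map_tags(lib_b, ref), gene_universe = ref$gene_ids)
de <- call_degs(prof_a, prof_b)
table(de$call)
top_table(de, n = 10)
```
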