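---
title: "Measuring imprinted versus random X-inactivation from hybrid-cross RNA-seq"
author: "xciallele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring imprinted versus random X-inactivation from hybrid-cross RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciallele)
```

## The measurement problem

In female mouse preimplantation embryos, X-chromosome inactivation (XCI) is
imprinted: the paternally inherited X is silenced in every cell, coated by
Xist RNA expressed from that same X. Perturbations of the Polycomb
repressive complex 2 (notably loss of oocyte-deposited, "maternal" EED)
can convert this parent-of-origin pattern into random XCI, where each cell
silences either X. Distinguishing the two regimes from bulk embryo RNA-seq
requires allele-resolved expression: in a hybrid cross whose maternal X
carries one strain haplotype (129/S1-like, close to the reference) and
whose paternal X carries a divergent haplotype (JF1/Ms-like, ~1 SNP per
250 bp of transcribed sequence), every read overlapping a SNP can be
attributed to one parental chromosome.

Under stable imprinted XCI, X-linked "subject" genes show almost
exclusively maternal expression and the Xist-like gene almost exclusively
paternal expression. Under a random mosaic, both drift toward 50%.
Autosomal genes sit at 50% in every regime and act as internal controls.
Genes that escape silencing ("escapers") retain partial expression from
the inactive X and sit in between.

## Pipeline model and contracts

The pipeline has five computational stages, each exported both as plain
functions and as file-level `stage_*()` drivers used by the `analysis/`
scripts:

1. **Pseudo-genome construction** (`substitute_snps()`): each strain's SNP
   alleles are substituted into the reference, producing two equal-length
   in-silico genomes that differ from the reference exactly at the
   substituted sites. Only single-nucleotide substitutions are accepted;
   a reference-allele mismatch or duplicated site is a hard error because
   it signals inconsistent inputs. `strain_transcriptome()` concatenates
   exons (reverse-complementing minus-strand genes), so the per-gene
   Hamming distance between the two strain transcriptomes equals the
   gene's exonic SNP count — a property the tests assert.

2. **0-mismatch allelic assignment** (`index_transcriptome()`,
   `assign_all()`): every read is searched for exact full-length
   occurrences in both strain transcriptomes, in both orientations, via a
   k-mer seed index (default k = 25) with full verification of each
   candidate. A read hitting one locus in one strain only is `maternal` or
   `paternal`; the same single locus in both strains is `shared` (a
   SNP-free span — counted in totals, never in allelic counts); more than
   one distinct (gene, offset) locus is `multimapped` and excluded
   entirely; no hit is `unmapped`. Matching is transcript-space substring
   search rather than spliced genome alignment: the property that matters
   downstream — a SNP-overlapping read matches exactly one strain under a
   0-mismatch rule — is preserved, while splice-aware mapping of real
   genomes is out of scope. Multi-mapping is defined at the gene level and
   conservatively includes repeated offsets within one gene. Orientation
   is searched but never used for assignment, since allele identity is
   strand-independent.

3. **Allelic quantification** (`count_snp_alleles()`,
   `gene_allelic_ratio()`, `allelic_expression()`): allelic reads
   increment every SNP they cover on their assigned haplotype. SNPs with
   at least `min_snp_reads` allelic reads (default 10, inclusive) are
   retained; a gene is *informative* when it has at least one retained
   SNP. The gene's paternal percentage is the unweighted mean over its
   retained SNPs. Totals (maternal + paternal + shared reads per gene)
   are normalized to reads per million mapped and split as
   `paternal_norm = total_norm * pct / 100`,
   `maternal_norm = total_norm - paternal_norm`, i.e. the total is
   apportioned by paternal/(maternal+paternal). The 10^6 scale is a
   convention; it cancels in every ratio and comparison. Maternal plus
   paternal components reconstruct the total to within 1e-9 relative
   tolerance by construction, and the tests enforce it.

4. **Group statistics** (`embryo_mean_paternal()`, `welch_test()`,
   `student_test_two_tailed()`, `order_genes_by_reference_group()`):
   comparisons use only genes informative in *all* samples. Each embryo is
   summarized by the unweighted mean paternal percentage over that gene
   set; genotype groups are compared pairwise with Welch's two-sample t
   test (group sizes and variances differ between genotypes), while
   normalized maternal/paternal expression and imaging proportions use
   the two-tailed Student t test. No multiple-testing correction is
   applied to the primary output (raw pairwise p-values are reported); a
   Bonferroni column is appended as clearly optional extra output. Heat
   map rows are ordered by the reference (fl/fl) group's mean, ties
   broken lexicographically so the order is deterministic.

5. **Side analyses**: allele-specific FISH probe design and nuclear IF
   quantification, described below.

## What the synthetic generator emulates

`make_toy_reference()` builds one autosome and one X chromosome with
two-exon genes (800 bp transcripts by default) and exonic strain SNPs at
1/250 per base; each gene is guaranteed at least one exonic SNP by
redrawing its placement if needed. One X-linked gene is flagged Xist-like;
every fifth remaining X gene is an escaper.

`simulate_embryo()` draws per-gene read counts from a negative binomial
(dispersion 0.1) around `mean_depth`, then assigns each read's haplotype
from the expression weights implied by the embryo's per-cell
X-inactivation state mixture:

* fl/fl, fl/-, -/- females: all cells paternal-X-inactive (imprinted);
* m-/- females: 50/50 mosaic of paternal-X-inactive and
  maternal-X-inactive cells (random XCI);
* mz-/- females: 35/35/30 with the third state expressing Xist from both
  X's and silencing both;
* males carry only the maternal X; in mutants half of the cells
  ectopically express Xist from (and silence) that X.

An inactive-X allele keeps `1 - silencing_efficiency` of its expression
(defaults: subject 0.92, escaper 0.25, autosomal 0); the Xist-like gene is
expressed only from inactive X's. Reads are exact substrings of the
appropriate strain transcript, then perturbed by uniform substitution
errors (default 0.001/base), which under the 0-mismatch rule mostly become
unmapped — mirroring how strict mapping discards errored reads.

Deliberate simplifications, hence what passing tests do **not** show about
real data: single-end 50 bp reads (no fragments or pairs), no splicing
isoforms or indels, no mapping bias between strains, no quality-score
model, and silencing applied as a single per-class efficiency rather than
a per-gene distribution. The simulation validates the *logic* of allelic
quantification, not aligner behaviour on real genomes.

### Chosen scales and defaults

The default run mirrors the modelled experiment's design: 4 embryos each
of fl/fl, fl/- and -/-, 5 of m-/-, 3 of mz-/-, all female, over 40
X-linked and 20 autosomal genes. `mean_depth` defaults to 600 reads per
gene: with 800 bp transcripts and 50 bp reads this yields roughly 15-40
allelic reads per SNP even for strongly silenced genes in mz-/- embryos,
so the >=10-read SNP filter reflects the intended semantics rather than
sheer shallowness — at much lower depth the informative-in-all-samples
intersection becomes dominated by escapers, which distorts group means.
This emulates the deep embryo libraries the design assumes; the filter
itself is never relaxed. The whole default run (~350k reads, 20 embryos)
completes in about a minute on one CPU and is byte-identical on rerun
with the same master seed, from which every embryo seed is derived.

## Allele-specific FISH probe design

`design_probe_panel()` encodes the probe scheme for discriminating Xist
RNA from the two X's in situ. For each of five panel SNPs (shared between
strains), two 28-nt detection oligos are emitted — reverse-complementary
to the strain transcript window, differing from each other only at the
polymorphic base, which sits at position 5 from the oligo's 5' end — plus
one unlabeled mask oligo complementary to the detection oligo's 3'
portion. The mask leaves a 9-10 nt free window around the SNP: a duplex
that short is destabilized by a single mismatch, so each oligo hybridizes
detectably only to its own allele. Maternal-strain oligos carry the
Quasar 570 label and paternal-strain oligos Quasar 670 (metadata only);
the mix sheet records 5 nM per detection oligo and 10 nM mask, a 1:1
mask:detection pairing. `validate_discrimination()` checks every free
window: perfect match to its own strain, exactly one mismatch (at the
SNP) to the other.

Design choices where the scheme is open: oligo length is not dictated by
the chemistry description, so 28 nt (a typical smFISH oligo length) is
the configurable default; when more usable SNPs exist than needed, a
greedy maximum-spacing rule spreads the panel along the transcript; SNPs
whose probe window would contain a second SNP, or which sit too close to
a transcript end, are skipped with a warning because they would break the
position-5-only discrimination and the shared mask.

## Nuclear IF quantification

`segment_nuclei()` reproduces a parameter-free DAPI threshold workflow:
Otsu's method (pluggable) binarizes the DAPI channel and connected
components become nucleus ROIs. Touching nuclei merge into one ROI — the
same documented limitation as threshold-based counting in imaging
software, so the synthetic generator places non-overlapping nuclei when a
known count is required. `measure_embryo()` subtracts the mean of a
non-nuclear background region from each nucleus mean per channel
(subtraction is linear in gain and invariant to offset, which the tests
assert) and averages nuclei into a per-embryo mean. `stage_embryo()` bins
embryos by cell count — 2-3, 4-5, 6-10 and 14-19 cells — and maps
anything else (1, 11-13, 20+) to "unstaged" rather than inventing a
nearest bin. Processing is 2D on single planes and images are used
without deconvolution, a stated simplification of voxel-based 3D
measurement.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and closed throughout, the R/Bioconductor
  convention (IRanges, Biostrings); VCF and GTF are already 1-based, so
  I/O performs no conversion.
* An uncovered SNP is reported with counts (0, 0) and an undefined
  percentage; a gene with no retained SNP is non-informative — a state,
  not an error. An empty informative intersection warns and returns an
  empty set.
* `mapped_total = 0` is a hard error in normalization (nothing to
  normalize by); zero-expression genes simply yield zero reads.
* t tests on two constant, equal groups return statistic 0 and p = 1;
  constant unequal groups are an error (the statistic is undefined), as
  are groups smaller than 2.
* Reads containing N can never match under the 0-mismatch rule and are
  unmapped by definition. Ambiguity codes are permitted in the reference
  but variants may not fall on them.
* Ties in heat-map ordering break by gene id; all orderings and file
  outputs are deterministic under a fixed seed.

## Known limitations

Real-data effects not modelled here: reference/mapping bias between
strain genomes, Xist's internal repeats (which depress its usable SNP
coverage), splice isoform variation, PCR duplicates and library
composition effects, and cell-to-cell depth variation within an embryo
(the state mixture is applied at the read level, which is equivalent in
expectation but ignores per-cell sampling covariance). Group tests
operate on per-embryo summaries, so they inherit the small-n behaviour of
t tests on 3-5 samples per group.
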