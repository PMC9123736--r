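---
title: "Bulked-segregant SNP-index scans from reduced-representation sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant SNP-index scans from reduced-representation sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slafbsa)
```

## The problem

Mapping the loci behind a quantitative trait in an outcrossing crop — here,
bast fiber content in hemp — is expensive if every plant must be genotyped.
Bulked segregant analysis (BSA) sidesteps this: pool DNA from the plants at
the two phenotypic extremes of a segregating population and sequence the two
pools. At loci unlinked to the trait the two pools carry the same allele
frequencies; near a causal locus the frequencies diverge. Combined with a
reduced-representation library (SLAF: restriction fragments in a narrow size
window, sequenced deeply), one cross and two pools give genome-wide marker
coverage at a fraction of whole-genome cost.

`slafbsa` implements that workflow end to end: in-silico digest design,
phenotype bulking, a staged hard-filter cascade for the pooled variant
calls, the SNP-index / Δ(SNP-index) scan with permutation thresholds,
candidate-region calling with gene annotation, and a forward simulator of
the whole experiment so each stage can be validated without external data.

## The statistic

For a biallelic site with bulk read depths $(r, a)$ (reference, alternate),
the SNP-index of a bulk is $a / (r + a)$: the fraction of reads carrying
the oriented allele. The scanned quantity is

$$\Delta(\text{SNP-index}) = \text{index}_{\text{high}} -
  \text{index}_{\text{low}},$$

smoothed by a sliding window value $m$: the arithmetic mean of
Δ(SNP-index) over 10 consecutive SNPs, advanced one SNP at a time and never
spanning chromosomes. Sites where a bulk has zero depth are masked, not
scored as zero — a zero would fabricate signal.

Significance is judged against a simulated null for the mating design. For
an F1 pseudo-testcross (two heterozygous outcrossing parents; informative
markers segregate 1:1), each replicate draws, per window SNP and per bulk,
an unlinked-marker pool frequency as the mean of `bulk_size` Bernoulli(1/2)
plant doses, then binomial read counts at the per-site depths, and finally
the window mean $m$. 10,000 replicates give the null distribution of $m$;
thresholds are two-sided nearest-rank quantiles of $|m|$ at 0.90 / 0.95 /
0.99. An F2 design (doses 0, ½, 1 with probabilities ¼, ½, ¼) is available
through `design = "F2"`. The per-site depths are resampled from the data by
default, which preserves the observed depth distribution; a constant-depth
mode exists for controlled experiments. An empirical fallback —
the 99th nearest-rank percentile of the observed $|m|$ — is also reported,
because a scan with no window above the simulated threshold still needs a
principled way to rank regions of interest.

Nearest-rank percentiles are used everywhere (rather than interpolating
quantile estimators) so that thresholds are exactly reproducible across
platforms and are always realized values of the statistic.

## The filter cascade

Pooled variant calls pass five hard filters, applied in a fixed order with
each removed site attributed to the first stage it fails:

1. **Multiallelic** — more than one alternate allele.
2. **Low support** — either bulk's total depth below 4 (a `support_mode`
   flag switches to thresholding the summed depth).
3. **Uniform pools** — both bulks show the same major allele and exactly
   equal SNP-index; such sites cannot carry bulk contrast. This is the
   weakest rule consistent with discarding sites of identical pool
   genotype, and at integer depths it is deliberately conservative.
4. **Parental inconsistency** — an allele supported by ≥ 4 reads in a bulk
   that appears in neither parent genotype cannot have been inherited;
   the site is treated as a calling artifact. When both parents are
   uncalled the site is removed under `strict_parents = TRUE` (default)
   and passed otherwise.
5. **Caller quality** — `QUAL < 30`, `QD < 2.0`, `FS > 60.0` or
   `MQ < 40.0`, applied exactly at those bounds.

The ledger satisfies `total == retained + Σ removed` *by construction* (its
constructor refuses anything else), and because every rule is defined
per-record and independently of the others, permuting the stage order can
only move counts between stages — the retained set is invariant, which the
test suite checks. For reporting, the last two stages are also presented as
one combined column, matching the shape in which such filtering tables are
conventionally published. Read-level QC (drop reads with > 10% undetermined
bases, or with ≥ 50% of bases at phred Q ≤ 10) is provided for FASTQ input;
the 50% bound is taken inclusively, the conservative reading.

## Digest design

`digest_sequence()` cuts at the union of both enzymes' recognition sites
(built-ins: RsaI `GT^AC`, HaeIII `GG^CC`, both blunt palindromic cutters, so
a forward-strand scan is complete). Fragments tile each sequence exactly —
lengths sum to the sequence length, no gaps or overlaps — and the digest is
invariant to enzyme order. Motifs never match across `N`. Size selection
keeps fragments of 314–364 bp inclusive; the `flank_rule` controls whether
tags must have two enzyme-cut ends (`internal_only`, the default: a
sequencing tag needs two ligatable ends), two *different* enzymes
(`mixed_enzymes`), or any ends (`any`). Published SLAF tag counts do not
state their flank convention, so all three are first-class options. Repeat
content is measured against soft-masked (lowercase) reference intervals and
gene coverage against GFF3 gene features; both are reported per enzyme
combination to support digest design the way library-prep screens do.

Coordinates are 0-based half-open internally and in BED output; GFF3 and
VCF I/O convert at the boundary.

## The synthetic experiment

`simulate_bsa_experiment()` forward-simulates the full design: 305 F1
plants from two heterozygous parents, 2,000 markers on a 100 Mb
chromosome, one causal locus, a 0–100% trait, extreme bulks of 30, pooled
sequencing at Poisson mean 45X per bulk and 10X per parent. Choices worth
knowing about:

* **Marker design.** Each parent is heterozygous at 45% of markers,
  independently, giving the pseudo-testcross mixture (het in one parent →
  1:1 segregation; het in both → 1:2:1). The causal marker is forced
  heterozygous in the male parent and homozygous reference in the female,
  so its alternate allele segregates 1:1.
* **Phase coupling.** A signed window mean is only informative if alternate
  alleles near the causal locus tend to lie on the same parental haplotype
  as the causal allele. In a wide cross whose reference genome derives from
  one ancestral background — the situation of a fiber × drug-type hemp
  cross mapped against a drug-type assembly — they do. The generator models
  this with `phase_coupling` (default 0.95): the probability that a het
  marker's alternate allele sits on the causal haplotype. At 0.5 the phase
  is random and the signed scan is structurally blind, which is a real
  failure mode of F1 BSA worth simulating deliberately.
* **Recombination.** Haldane model (crossovers as a Poisson process, no
  interference) at 2 cM/Mb, a typical plant rate. On a 100 Mb chromosome
  this yields a ~200 cM map, so distal markers genuinely decouple from the
  QTL. A shorter chromosome leaves everything linked to everything and
  makes "candidate region" degenerate. `unlinked = TRUE` makes markers
  segregate independently, the configuration matched by the permutation
  null and used for type-I calibration.
* **Trait model.** `trait = 28 + 5 × dose + N(0, 2.5)`, clipped to
  [0, 100]: a baseline and spread consistent with a fiber-content range of
  roughly 11–46% in the F1, and a locus effect twice the environmental SD —
  a major QTL, which is the regime bulked designs are suited to detect.
  Phenotypes are emitted as stem and bast weights so that the
  fiber-content formula (bast/stem × 100) is exercised by the readers.
* **Sequencing.** Binomial allele sampling at the pool frequency with an
  allele-flip error of 0.001; caller annotations drawn from clean ranges
  with a configurable fraction (default 2%) of planted hard-filter
  violations so the cascade always has work to do.

What the generator does *not* emulate: real SLAF tag dropout and PCR
duplicates, linkage disequilibrium structure within parents beyond the
single phase-coupling parameter, multiple QTL (available but off by
default), segregation distortion, and hemp's sex chromosomes. Passing tests
therefore demonstrate the statistics and bookkeeping are right under the
stated model, not that any particular biological dataset will behave.

## Region calling

Candidate regions are maximal runs of windows with $|m|$ at or above the
threshold. Boundaries are anchored at member SNP positions (first SNP of
the first window to last SNP of the last), which keeps region endpoints
reproducible and tied to observed markers. Because step-1 windows overlap
by 9 SNPs, the SNP spans of nearby runs can themselves overlap; overlapping
spans are unioned so that regions on a chromosome are always disjoint.
`max_gap_snps` (default 0) optionally bridges short below-threshold dips:
linked signal forms a plateau whose window means dip with local marker
composition, and bridging up to one window width (10) is the setting used
in the package's own recovery studies. Genes are assigned to regions on
≥ 1 bp overlap, strand-ignorant, with half-open interval semantics — a gene
abutting a region boundary does not overlap it.

## Numerical and degenerate-input choices

* Zero-depth bulks: masked points, excluded from windows (never zero).
* Chromosomes with fewer than 10 usable SNPs contribute no windows.
* Empty digests, empty window sets and empty region sets are well-typed
  empty results; the empirical threshold refuses an empty window set.
* All randomness flows through explicit seeds; one run seed fans out to
  per-stage seeds, so stages are individually reproducible and a pipeline
  run with the same config and seed is byte-identical (the manifest hashes
  are compared in the tests).
* Tie-breaks: bulk selection orders by (trait, plant id) in one total
  order, so bulks are disjoint even under massive ties and invariant to
  input row order.

## Problem sizes used in the test suite

The shipped tests run the full pipeline at 2,000 markers × 305 plants per
seed (about a second per seed): 20 seeds for causal-locus recovery, 10
seeds of effect-free unlinked data for type-I calibration, and 10,000
permutation replicates per threshold. These sizes were chosen as the
smallest at which the binomial and Monte-Carlo error bars in the
assertions are meaningfully tight.

## Known limitations

* The parental-inconsistency rule is one defensible reading of vendor-style
  "recessive source" filters; published pipelines do not specify their
  exact algorithm, so counts at that stage are implementation-defined
  (the retained-set invariance under stage permutation still holds).
* With random phase (`phase_coupling = 0.5`) the signed scan loses power by
  design; a magnitude-based statistic would be the remedy but is a
  different method with different null behavior, and is out of scope.
* The permutation null assumes unlinked markers. On densely linked maps
  neighboring windows are correlated and the genome-wide exceedance rate
  at confidence $c$ exceeds $1 - c$; this is a property of windowed BSA
  nulls generally, and is why the type-I calibration uses independently
  segregating markers.
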