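---
title: "Allele-resolved chromatin motif discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved chromatin motif discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromotif)
```

## The model

Chromatin accessibility assayed by FAIRE-seq is read out here entirely
through allele-resolved depth at phased heterozygous SNPs. The underlying
assumptions are:

* **Depth imbalance reflects allelic chromatin state.** If one haplotype is
  nucleosome-depleted and the other is not, reads pile up on the accessible
  allele. A fold change > 2 with the greater depth >= 10 is treated as a
  hard call of a differential chromatin-state region (DCSR); fold < 1.5
  with depth >= 5 as a balanced control (NDCSR). These are threshold rules,
  not a probabilistic imbalance model: no binomial test and no FDR control
  are applied at the calling step, by design.
* **The focal base is the candidate cause.** A DCSR pair consists of the
  two 41-base haplotype windows around the SNP, identical except at the
  centre (and at any other phased variant that falls inside the window,
  which is substituted on its own haplotype and flagged). A k-mer whose
  occurrence differs between the groups therefore usually does so because
  the SNP completes the word on one allele and breaks it on the other.
* **Paired testing.** For each k-mer, per-pair occurrence counts in the
  inaccessible (x) and accessible (y) windows are compared with a paired t
  statistic on d = x − y, with the sample (n − 1) standard deviation and a
  two-sided p-value on n − 1 degrees of freedom. Two-sided is chosen
  because depleted-in-accessible and enriched-in-accessible words are both
  biologically meaningful (activating versus repressive binding), and both
  directions are reported. Counting is forward-strand only on the stored
  windows; the reverse complement is reported as metadata. Merging strand
  counts would double-count palindromes such as CACGTG.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `flank` | 20 | bases | 41-base windows centred on the SNP; large enough for a 10-mer to span the focal base at any offset |
| `dcsr_fold`, `dcsr_depth` | > 2, >= 10 | fold, reads | the published DCSR operating point; strict on fold, inclusive on depth |
| `ndcsr_fold`, `ndcsr_depth` | < 1.5, >= 5 | fold, reads | balanced-control operating point; equal depths (fold 1) qualify |
| `kmin`..`kmax` | 6..10 | bases | the exhaustive candidate space (1,396,736 words) |
| `p_max` | 0.01 | — | raw paired-t selection threshold (strict); no multiplicity correction by design, a BH column is emitted for information only |
| `rate_min` | 0.01 | fraction | occurrence rate (fraction of windows with >= 1 hit) must exceed 1% in at least one group, suppressing ultra-rare words |
| `homology_min`, `evalue_max`, `tfbs_max_len` | 0.8, 10, 30 | fraction, —, bases | annotation gates: identity over the k-mer length must exceed 80%; E <= 10 is permissive; sites > 30 bases are discarded as multi-site concatenates |
| `fpkm_min` | 1 | FPKM | TFs below this are treated as unexpressed and removed from annotations |
| `promoter_up` | 2000 | bases | promoters are the strand-aware interval [TSS − 2000, TSS); precedence promoter > genic > intergenic |

## Numerical and degenerate-input conventions

* **Zero denominator in fold change**: depth (d, 0) has fold +Inf, which
  can qualify as a DCSR (given the depth floor) and never as an NDCSR;
  (0, 0) qualifies for nothing.
* **Degenerate variance in the t-test**: if every paired difference is
  equal, the statistic is 0 with p = 1 when the common difference is zero,
  and signed infinity with p = 0 otherwise. The latter occurs for a
  perfectly separating motif at small n.
* **Ties**: equal depths assign the accessible label to the paternal
  allele, deterministically; equal p-values order lexicographically by
  k-mer. Both choices exist purely for reproducibility.
* **N bases**: windows containing N after substitution are excluded from
  counting (exact matching only; N never matches). Edge SNPs whose window
  would run off the chromosome are rejected, never truncated.
* **Occurrence rate** is defined as the fraction of windows with at least
  one hit, not mean hits per window. Reported per-group rates for known
  motifs are naturally on this scale; the alternative reading (mean count)
  differs only for words hitting multiple times per 41-base window, which
  is rare for k >= 6.
* **E-values** for 6–10-base queries are computed from the ungapped
  Karlin–Altschul formula K·m·n·exp(−λS) over a local alignment with
  match +1 / mismatch −2 (λ = 1.3327, K = 0.621). At these query lengths
  the E-value is a coarse gate; the homology threshold is the operative
  filter, so the annotation result is insensitive to the precise E-value
  parameterisation.
* **Perfect-match read filtering** (`depth_from_alignments`): on
  haploid-reference alignments a read carrying the non-reference allele
  necessarily has one mismatch at the SNP itself, so "no mismatch" is
  enforced *outside the focal base*: allowed NM is 0 for reads whose SNP
  base equals the reference and 1 for reads carrying the other allele.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates: a uniform-composition random genome at GC
0.41; 2,000 phased het SNPs over 2 × 1.35 Mb (about one het per 1.35 kb,
a realistic human density, so a realistic ~3% of windows contain a second
variant within 20 bases); per-allele depths drawn from a negative binomial
(mean 20, size 5), the standard over-dispersed model of sequencing
coverage; and, at 30% of SNPs, a planted CACGTG completed by one
haplotype's base at a uniformly random in-motif offset and broken by the
other's, with the intact allele's depth mean multiplied by 5. SNP
positions keep pairwise gaps greater than the motif length so one planted
footprint never overwrites another SNP's allele. All randomness flows from
a single seed recorded in every output header, and equal seeds give
byte-identical files.

Deliberately *not* emulated: read-level sequencing (FASTQ, alignment,
mapping bias — depth is drawn directly; the alignment-counting path is
exercised by small hand-written SAM fixtures instead), linkage between
neighbouring SNPs, local GC or repeat structure, indels, and genuine
TF-occupancy biology. Passing tests on this generator therefore
demonstrate the correctness and power of the *procedure* under its own
model, not that real FAIRE-seq data will yield motifs of the same
strength.

The test suite uses scaled-down problem sizes chosen to keep each run in
seconds-to-minutes: 300-SNP simulations for structural checks, 500 DCSR
pairs with 6-mers only for the null calibration, and 20 seeds at the
default 2,000-SNP configuration for planted-motif recovery.

## Known limitations

* **The paired t-test is conservative on this design.** Because the two
  windows of a pair differ at essentially one base, a k-mer's paired
  difference is nonzero only when a hit spans the SNP on exactly one
  allele. Under the null this happens for only a handful of pairs per
  k-mer, so the difference vector is sparse and integer-valued, the t
  statistic is strongly discrete, and null p-values concentrate far above
  the nominal level: the realised fraction of null k-mers below p = 0.01
  (measured by the acceptance suite) falls well short of 0.01. The
  procedure is therefore *anti*-conservative in no regime we observed —
  selected motifs are if anything under-called — but nominal type-I
  calibration should not be assumed, and the recovery experiments show
  the conservativeness costs little power against real effects.
* Overlapping DCSR windows from qualifying SNPs closer than 41 bases are
  all retained (none are merged), so a single haplotype block can
  contribute correlated pairs.
* Reads spanning several het SNPs are counted at each SNP independently;
  conflicting allele assignments within one read are not reconciled.
* Region classification depends entirely on the supplied gene models;
  overlapping annotations resolve by the promoter > genic precedence rule.
* Annotation coverage is bounded by the supplied TFBS collection and
  expression table; with small collections most motifs remain honestly
  unannotated rather than force-matched.
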