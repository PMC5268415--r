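---
title: "Gene-body 5hmC enrichment analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-body 5hmC enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

5-hydroxymethylcytosine (5hmC) is the first oxidation product of
5-methylcytosine on the TET-mediated demethylation path. In adult
mammalian tissues it accumulates preferentially in the bodies of
transcribed genes, and chemical-capture sequencing (hMeDIP-style
enrichment of glucosylated 5hmC fragments against an input control)
yields, per sample, a set of enriched genomic regions. `hmcscan`
implements the downstream analysis of such data across a multi-tissue,
two-sex study design:

1. **Island calling** — a window-clustering caller over fragment BED
   files, producing enriched regions ("islands") against an input
   control.
2. **Intragenic coverage** — for every annotated gene, the fraction of
   its span (TSS to TTS, introns included) overlapped by the merged peak
   set of each sample. This genes-by-samples matrix is the central
   statistic; everything downstream consumes it.
3. **Profiles and summaries** — scaled metagene profiles around gene
   bodies, five-level coverage classes, genome/chromosome/biotype
   summaries.
4. **Expression integration** — TMM-normalised log2 CPM from a count
   matrix, Spearman sample similarity, hierarchical clustering of
   gene-body enrichment patterns into coverage-ordered clusters C1–C5,
   rank tests of marked vs unmarked genes, organ- and sex-specific gene
   calls, and the two exception classes of the coverage–expression
   association (expressed-but-unmarked; marked-but-silent).

## The island caller

Fragments deduplicated at a redundancy threshold of 1 are reduced to
points (read start shifted by half the fragment size along the strand)
and counted in non-overlapping 100 bp windows. Window counts are
compared to a Poisson background with rate

$$\lambda_{bg} = \frac{N \cdot w}{f_{\text{eff}} \cdot G},$$

where $N$ is the retained fragment count, $w$ the window size, $G$ the
genome length, and $f_{\text{eff}}$ the effective (mappable) genome
fraction. A window is *eligible* when its count $c$ satisfies
$P(X \ge c \mid \lambda_{bg}) < p_0$. Eligible windows separated by at
most the gap size are joined into islands spanning first to last
eligible window; the island score is
$\sum_{w \in \text{eligible}} -\ln \text{Pois}(c_w; \lambda_{bg})$.
Each island is then tested against the input control: the expected
treatment count is the control count scaled by the library-size ratio,
floored at the background expectation for the span (so islands with a
zero control count cannot reach $p = 0$), with a Poisson upper-tail p
and Benjamini–Hochberg adjustment across islands. Islands with
$q < 0.01$ are retained.

Defaults follow the published use of this algorithm family on 5hmC
capture data: window 100 bp, fragment size 200 bp, gap 200 bp (100 bp
supported through the same parameter), FDR 0.01, redundancy 1. Two
values are not published for this data type and are set to the
conventional choices of the algorithm family, both configurable:
$p_0 = 0.2$ and $f_{\text{eff}} = 0.74$. No attempt is made to
replicate any specific caller implementation byte-for-byte; the
properties that matter — no islands on background-only input, reliable
recovery of several-fold enrichments — are asserted by simulation in
the test suite.

## Coverage, classes, and metagene profiles

A gene's intragenic region is its full annotated span. Gene spans are
not exon-flattened and overlapping genes are scored independently; this
matches the TSS-to-TTS definition of the gene body and keeps every gene
directly comparable regardless of annotation depth. Coverage classes
partition $[0,1]$ with lower-inclusive boundaries: none ($=0$), low
($<0.20$), intermediary ($[0.20, 0.50)$), high ($[0.50, 0.80)$), very
high ($\ge 0.80$). The boundary convention at exactly 0.8 is chosen so
the five classes are disjoint and exhaustive.

Metagene profiles use 25 fixed 100 bp bins per 2.5 kb flank and 40
length-scaled bins across the body (both configurable). Body-bin
boundaries are computed with integer arithmetic
($\lfloor kL/B \rfloor$) so that a minus-strand gene's profile is the
*exact* mirror of its strand-flipped twin — a property the test suite
asserts to machine precision. Flank bins truncated at a chromosome
boundary keep their remaining width as denominator; bins clipped away
entirely drop out of the average rather than contributing zeros.

## Expression model

Normalisation is the trimmed mean of M-values: the reference sample is
the one whose 75th-percentile count fraction is closest to the mean of
those fractions; per sample, log ratios (M) and average abundances (A)
against the reference are computed over genes nonzero in both, the 30%
most extreme M and 5% most extreme A are trimmed, and the factor is the
precision-weighted mean of the retained M values, with factors rescaled
to geometric mean 1. The implementation is in this package and is
checked against an independent implementation of the same rule in the
test suite to $10^{-9}$.

log2 CPM is $\log_2\!\big((c + 0.5)/(L f + 1) \times 10^6\big)$ with
prior count 0.5. "Moderately to highly expressed" means log2 CPM of 2.5
or more (inclusive); the "expressed at all" threshold defaults to log2
CPM 0 (CPM 1). Group-level status uses the ALL-replicates rule — a
group is flagged only when every sample in it passes — because a single
discordant replicate should veto a categorical call; an ANY rule is
available by configuration.

## Clustering and gene-set statistics

Genes are clustered on their body-bin coverage vectors (flanks
excluded, matching the gene-body definition) with Euclidean distance
and Ward linkage (`ward.D2`), cut at $k = 5$, and relabelled C1–C5 by
strictly increasing mean coverage. The linkage is a design choice —
only "hierarchical clustering" is standard in this analysis tradition —
so complete and average linkage are available through the same
interface, and exact cluster sizes should not be expected to reproduce
across linkage choices. Cluster–expression association is summarised by
per-cluster medians/IQRs and the Spearman correlation between cluster
index and per-gene expression.

Set-membership percentages are rounded half away from zero to integers,
the convention used when reporting counts such as "294 of 540 (54%)".

## Specificity and exception calls

Organ-specific genes are called with a deterministic threshold rule:
moderately-to-highly expressed (log2 CPM $\ge 2.5$) in **every** sample
of one organ and below CPM 1 in **every** sample of the other. This
deliberately replaces a differential-expression model fit: the rule is
reproducible without tuning, and its strictness errs toward precision.
Sex-specific enrichment requires coverage $\ge \tau_{cov}$ (default
0.1) in every sample of one sex and exactly zero in the other,
genome-wide — sex chromosomes included, since the canonical positive
control (the X-inactivation transcript) is X-linked. Exception classes
run over autosomal protein-coding genes only: class 1 is
moderate-high expression in all samples with zero coverage in all
samples; class 2 is below the expressed threshold everywhere with
coverage in every sample (any overlap by default; a minimum fraction is
configurable). The two classes are mutually exclusive by construction.

## The synthetic study generator

The generator exists so that every stage is testable, with known truth,
without any external download. It mirrors the study design at toy
scale: 3 autosomes plus X and Y analogs (~30 Mb), ~1000 genes with
log-normal lengths clipped to 1–100 kb, 12 coverage samples (2 sexes ×
5 brain regions + liver) and 24 expression libraries (2 replicates).

**Coverage targets.** Per-gene fractions are drawn from organ-level
Beta marginals — brain Beta(2, 1.2), liver Beta(1.2, 2.5), reproducing
the brain > liver enrichment ordering — coupled through a Gaussian
copula that plants the relatedness hierarchy: thalamus and hypothalamus
nearly interchangeable, cerebellum the most distinct brain region,
liver weakly coupled to brain. Sex replicates of a region are almost
perfectly correlated, as in tissue from the same region.

**Peaks.** Peak lengths are Normal(800, 200) truncated to
[100, 3000] bp, calibrated to the ~800 bp mean enriched-region size of
this data type. Within a gene, peaks are placed without overlap by
stick-breaking the uncovered space into gaps whose expected sizes
decrease (quadratically) from the 5' to the 3' end, with the terminal
gap damped; this realises the 3'-skewed intragenic placement seen in
capture data, gives each gene exactly its target covered fraction, and
produces monotone rising metagene body profiles. Sex-chromosome genes
receive no peaks, except one X-linked analog covered only in female
samples; sparse background peaks are scattered over intergenic
autosomal space.

**Counts.** Counts are negative binomial,
$\text{NB}(\mu = 2^{a + b\,\text{cov} + e_g},\ \phi)$ with baseline
$a = 11$ (libraries of roughly 3 million counts — deep enough that one
stray read in a silent gene stays below CPM 1), slope $b = 1.5$,
dispersion $\phi = 0.1$, and a mild per-gene baseline
$e_g \sim N(0, 0.15)$. Housekeeping genes (12% of genes) are decoupled:
they hold a constant *share* of each library — the defining property of
constitutive expression, and the formulation that avoids spurious
negative coverage–expression correlation from library-depth differences.
Planted exceptions override the link only where the exception requires
it: class-1 genes follow the link at their planted zero coverage (hence
expressed but unmarked), class-2 genes are silenced at high coverage,
organ-specific genes follow the link in their organ and are silenced in
the other, and the X-linked analog is silenced in males. Planted set
sizes (1.2% / 0.8% exception classes, 2% / 1% organ-specific) keep the
off-link fraction of genes at the few-percent level characteristic of
these gene classes genome-wide.

**What the generator does not emulate.** Read-level error, mappability
and GC bias, exon structure, overlapping genes, annotation error, and
any coupling between gene length and expression. Passing recovery tests
therefore demonstrates that the pipeline's logic is correct under its
own stated model — not that real-data numbers (which depend on the
deposited datasets and on unpublished tool internals) would be
reproduced. Genome-scale figures from real data are treated as
qualitative calibration only.

## Numerical choices and degenerate inputs

* Interval arithmetic is delegated to `GenomicRanges`/`IRanges`;
  internally everything is a `GRanges` (1-based closed), converted at
  the BED (0-based half-open) and GTF (1-based closed) boundaries.
  Tests verify merge/overlap against a per-base boolean oracle.
* Wilcoxon tests use the exact null for $n_1 + n_2 \le 12$ without
  ties, otherwise the normal approximation with continuity and tie
  correction. Strata with fewer than 2 members per group are reported
  untestable rather than silently dropped.
* Zero-variance t-test inputs return a degenerate-variance flag (equal
  means: $t = 0, p = 1$; unequal: $p < 10^{-12}$) instead of dividing
  by zero.
* Clustering is deterministic for a fixed input order; C-relabelling
  re-sorts cluster means before assigning labels, so C1–C5 mean
  coverage is strictly increasing on every run.
* Empty inputs (no peaks, empty BED, background-only fragments) yield
  empty-but-well-formed results, not errors.

## Problem sizes

The default study (1000 genes, ~30 Mb, 12 + 24 samples) runs the whole
pipeline in well under a minute; the test suite uses 150–300-gene
studies for module tests and the full default for the end-to-end
recovery checks. The island-caller calibration uses a 1 Mb toy genome
with 15,000 fragments per arm and 50 replicates per condition. These
sizes were chosen so the planted effects are estimated with comfortable
margins while a complete run stays interactive.
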