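---
title: "Measuring transposable-element responses to exposure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transposable-element responses to exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teomics)
```

`teomics` measures how transposable elements (TEs) respond to environmental
exposures across chromatin accessibility, transcription and DNA methylation.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

## Coordinates and annotation

All internal coordinates are 0-based half-open; the GTF reader/writer and
the `rmsk` table reader convert at the boundary, so no function ever mixes
conventions. Only the four TE classes (DNA, LINE, SINE, LTR) are analysed;
simple repeats, satellites and low-complexity records are removed on input
because they are not mobile elements and would distort subfamily
backgrounds. Subfamily age is summarised by the youngest taxon in which the
subfamily occurs: `Mus_genus`/`Mus_musculus` map to the *Mus musculus*
clade, `Muridae`/`Murinae` to Muridae, `Glires`/`Rodentia` to Rodentia, and
everything older (or unmapped) to `Other` — three named clades are enough
because responsiveness is interpreted along the young-to-old axis.

Genome-background fractions for enrichment can be counted per copy or per
base pair. Copy counting is the default: the assignment unit everywhere else
(summits, TSSs, CpGs → one TE copy) is the copy, so a copy-based background
keeps numerator and denominator on one scale. `bp_total` sums copy lengths
without merging overlaps (RepeatMasker copies rarely overlap and the
statistic stays linear in the records); an interval-union option exists for
annotations where nesting is common.

## The negative-binomial differential test

Counts are modelled as NB with a log link, a library-size offset and a
single condition coefficient. Three choices deserve justification:

- **Dispersion.** Per-feature method-of-moments estimates (pooled across the
  two condition groups) are shrunk toward the common dispersion with weight
  proportional to the residual degrees of freedom against a prior of
  `prior_df = 10`. With 6 samples per group a raw per-feature estimate is
  far too noisy; full empirical-Bayes tagwise machinery is more than the
  contract needs. The shrinkage target and weight give a calibrated test:
  on 2,000 simulated null features (dispersion 0.1, 6 vs 6) the empirical
  P(p < 0.05) sits near 0.055, inside the 0.03–0.07 band the test suite
  enforces.
- **Test statistic.** A 1-df likelihood-ratio chi-square between the
  intercept-only and condition GLMs at the fixed shrunk dispersion. The GLM
  fits go through `stats::glm` with the `MASS::negative.binomial` family.
- **Fold change.** log₂ of normalized group means with a prior count of 0.5
  per group, so zero-count groups give large finite fold changes instead of
  infinities.

Tier thresholds (`tier_thresholds()`) are applied with strict inequalities
exactly as printed: subfamily expression FDR < 0.001 & |log₂FC| > 0.8;
subfamily accessibility FDR < 0.001 & |log₂FC| > 0.15; locus accessibility
(DAR) FDR < 0.01 & |log₂FC| > log₂ 1.5; transcripts FDR < 0.01 &
|log₂FC| > 1; chimeric FDR < 0.05 & |log₂FC| > log₂ 1.5. The subfamily tiers
additionally require median CPM > 100 in *either* condition — the prefilter
is read as an either-condition rule so that a subfamily silenced by exposure
(high in controls only) is still testable. The multiple-testing family is
all features of one tier within one sex-by-exposure contrast; contrasts are
analysed separately and cross-sex samples are never pooled. Normalization is
CPM by library size only — the intended inputs are consortium-normalized
counts, so TMM-style factors are out of scope.

## Summit and TSS assignment

A peak is TE-derived iff its single summit base lies inside a TE; a
transcript iff its strand-aware TSS base does. Half-open containment makes
the boundary unambiguous (a summit at a TE's `end` coordinate is outside).
When nested or overlapping copies contain the same base, the shortest
element wins — the innermost element is typically the youngest insertion and
the most plausible signal source — with leftmost-start and lexicographic
subfamily as deterministic tie-breaks. Genomic-feature labels use
any-overlap with precedence TSS > TTS > exon > intron > intergenic; TSS/TTS
windows default to ±1,000 bp (a conventional promoter-scale window; the
methodology does not pin a value, so it is a visible, configurable
parameter). cCRE labels take the element with the largest overlap, ties
resolved toward the more specific regulatory type (PLS > pELS > dELS >
DNase-H3K4me3 > CTCF-only). Hypergeometric p-values accompany enrichment
ratios as an addition — ratios alone are reported separately so they stay
comparable across analyses that print only ratios.

## Chimeric transcripts

The three filters are computed for *every* candidate regardless of earlier
failures, so the ledger is order-independent and each decoy can be checked
against exactly the filter it was built to violate. Interpretation choices:

- the junction quorum "at least 2 reads in individual sample" is read as
  ≥ 2 reads in *at least one* sample (default); the stricter every-sample-of-
  a-condition reading is available via `rule = "all_of_condition"`;
- the known-exon exclusion is strand-agnostic (more conservative — an
  antisense overlap also disqualifies a first exon as "novel"); a
  strand-aware switch exists;
- expression CPM is computed against the whole library (annotated plus
  novel transcript counts), not the novel set alone;
- category assignment tests same-strand exon-level overlap, because an
  antisense transcript inside a coding gene's intron belongs in the no-gene
  group; `TE_transcript` requires full coverage by the union of TE
  intervals, with the covering elements reported;
- ORFs are the longest ATG-to-stop frame in the spliced sequence, minimum
  300 nt (a common lower bound for a plausible product; no minimum is
  inherent to the method, so it is configurable), length reported including
  the stop codon, peptide excluding it.

## Motif scanning, exact p-values, conservation

PWM scores are log₂-odds against the background with a 0.01 pseudocount per
matrix cell; both strands are scanned. P-values are exact: the score
distribution of a random background window is computed by dynamic-programming
convolution on a 10⁻⁴-bit integer grid, which matches exhaustive 4^L
enumeration to 1e-12 for motifs up to length 8 in the test suite. One
consequence matters in practice: a 6-bp motif's best attainable p-value
under a uniform background is 4⁻⁶ ≈ 2.4 × 10⁻⁴, so the conventional 10⁻⁴
scanning threshold can never fire on a 6-mer. The scanner's default stays at
10⁻⁴ (the established convention for full-length PWMs); the pipeline passes
10⁻³ when scanning the synthetic 6-bp cores, which separates exact matches
(p ≈ 2.4 × 10⁻⁴) from single-mismatch windows (p ≈ 5 × 10⁻³).

Conservation is measured against the subfamily consensus by *pairwise*
global alignment of each copy (match +2, mismatch −1, gap of length L costs
4 + L, via `Biostrings::pairwiseAlignment`) rather than a progressive
multiple alignment: the quantities consumed — whether a motif hit projects
into the core region, and per-consensus-column identity — depend only on the
copy-to-consensus correspondence, and pairwise alignment is deterministic
and testable against a brute-force dynamic program. The core region is a
required input (it is defined graphically, not numerically, in the
literature this follows).

## Methylation

Sites need ≥ 20X coverage. Per-TE and per-subfamily methylation is the
unweighted mean of per-CpG ratios; "averaged methylation" does not specify
weighting, and the unweighted mean keeps deeply covered sites from
dominating (coverage-weighted pooling is available). The subfamily aggregate
averages over CpGs, not over copies — copies differ wildly in CpG content
and a copy-mean-of-means would weight a one-CpG copy as heavily as a
twenty-CpG copy. The paired Wilcoxon signed-rank test is exact (full
sign-assignment enumeration via convolution) up to 25 informative pairs,
with zero differences dropped and mid-ranks for ties, then a
continuity-and-tie-corrected normal approximation.

## What the synthetic data emulate — and what they do not

The generator's defaults describe the study conditions the package is
validated under: 2 chromosomes × 1 Mb; 43 subfamilies (5 DNA, 28 LINE, 5
SINE, 5 LTR — 28 LINEs so the planted methylation contrast has the same
number of pairs as the motivating analysis) × 50 copies of a 300-bp
consensus diverged at 5% per base; a sex × exposure design with 6 samples
per group and two exposures; NB counts with dispersion 0.1, log-normal(0,
0.2) library factors and ±2 log₂-unit effects planted on 10% of features;
500 peaks with 20% of summits inside TEs; one LTR subfamily carrying an
Ikzf3–Elf3–Elf3 motif run (AGGAAG/CTTCCT) in a 60-bp core, with 30% of its
copies motif-ablated and extra core divergence (rate 0.15) planted in the
ablated group; Beta-binomial methylation (concentration 50, NB coverage with
mean 35) with a −0.2 shift planted in the 28 LINE subfamilies of one
exposure arm; and chimeric transcripts of all four categories plus one decoy
per filter. Sub-generators draw from independent, label-derived RNG streams,
so identical configurations are byte-identical and adding a generator never
perturbs the others.

Planted male subfamily effects reuse the female feature set with 3 of 4
signs flipped, so the sexes respond discordantly and the fold-change
correlation is negative by construction — mirroring the sex-specificity the
method is meant to expose.

The simulation is deliberately idealized in ways that bound what passing
tests demonstrate about real data: placement is grid-based with TEs and
genes in disjoint bands except where geometry is planted, so assignment
stages face no ambiguous overlaps beyond the constructed ones; counts are
generated from the same NB family the test assumes (calibration on real
data, where normalization residue and outliers violate NB, will be worse);
peptides are assigned metadata rather than translated genome sequence
(except the one planted ORF cassette, which is written into the genome
base-exactly); motif instances are protected from random divergence so
planted presence is exact; and no read-level noise, mappability structure or
batch effects exist. Recovery rates on this data are upper bounds, and the
differential-calibration numbers are properties of the test, not of any
real experiment.

## Problem sizes

The test suite and acceptance script run the full pipeline on the default
2,150-copy dataset (about a minute), the calibration experiment on 2,000
null and 500 planted features, interval-oracle comparisons on 10⁴ random
instances per operation, and exact-enumeration cross-checks for motifs up to
length 8 and Wilcoxon up to 12 pairs — sizes chosen so every check is exact
or tightly powered while the whole suite stays in a few minutes.

## Known limitations

No batch or covariate adjustment in the GLM (single condition coefficient);
no TMM/quantile normalization; no multi-mapper-aware quantification
(count matrices are taken as given); no transcript assembly; no DMR
segmentation; peptide comparison is exact string identity, so biologically
silent variants count as "different".
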