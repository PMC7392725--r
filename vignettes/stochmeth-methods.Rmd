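---
title: "Models and methods behind stochmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stochmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochmeth)
```

## The scientific problem

MeDIP-seq enriches methylcytosine-bearing DNA fragments, so local read
density is a semiquantitative methylation signal. When a regulator is
depleted, methylation can change in two qualitatively different ways: a
*stochastic* component — random, direction-free gains (GoM) and losses
(LoM) scattered genome-wide that cancel in aggregate — and a
*deterministic* component targeted to specific sequences such as
transcription-factor binding sites. This package separates the two from
paired control/knockdown MeDIP read sets, and pushes the same logic down
to single alleles: a stochastic methylation state implies random allelic
choices, visible as allelic imbalance and even allelic flips at
heterozygous sites.

## Bin signals and the Diff/Sum statistic

Signals are computed on fixed 200 bp bins. A read counts toward a bin when
at least 50% of the read overlaps it, boundary inclusive (the bedtools
`-f 0.5` rule); with 150 bp reads this assigns a read to one bin except
for exact 50/50 splits, which count in both. Depth differences between
samples are removed before comparison, either by random subsampling of the
larger read set to the smaller one (seeded, the default in the pipeline)
or by a multiplicative scale factor.

For each bin with combined signal `ct + kd >= 3` the change statistic is
`(kd - ct)/(kd + ct)`, bounded in [-1, 1]. Frequency histograms use
centers at multiples of 0.1 (configurable). The expected
no-net-change distribution replaces the frequencies at ±b by their mean,
leaving the 0 bin untouched — a mass-preserving, idempotent operation
whose fixed points are exactly the symmetric histograms.

Two deviation summaries are reported, because "mean of differences" over a
mirrored pair is ambiguous: `mean_diff_freq`, the mean over histogram bins
of observed-minus-expected frequency (identically zero whenever mass is
preserved, kept as a degeneracy check), and `mean_shift`, the
frequency-difference-weighted mean Diff/Sum in Diff/Sum units, whose sign
reads directly as a net loss (negative) or gain (positive) of methylation.
The Kolmogorov–Smirnov comparison runs over the bin-ordered CDFs of the
two histograms; since paired binned frequencies do not define a sample
size, the asymptotic two-sample p-value uses the number of histogram bins
as the effective n. This is documented as approximate and is used as a
deviation diagnostic, not as a calibrated test.

## Entropy as a stochasticity measure

At each |Diff/Sum| magnitude bin, regions are in one of two states — GoM
or LoM — and the binary Shannon entropy of that state,
`H = -p log2 p - (1-p) log2 (1-p)` with `p` the GoM fraction, measures how
random the change of that magnitude is: `H = 1` bit at equal presence,
`H = 0` at exclusivity, by construction. Regions enter the profile when
sequenced at least 3 times in CT and KD combined and at least twice in one
of the samples (`max(ct, kd) >= 2`); regions at exactly 0 carry no state
and are excluded from `p`. A deterministic, direction-consistent target
set concentrated at some magnitude band depresses entropy there — the
package's planted-recovery tests rely on exactly this signature.

## Motif scanning and enrichment

PFM counts become probabilities with a per-cell pseudocount of 0.1
(`(count + 0.1) / (total + 0.4)`), and log2-odds scores against a 0-order
background, by default estimated from the scanned sequences and
symmetrized over complementary bases so one null distribution serves both
strands. Scores are rounded onto a lattice of 0.01 log2-odds units; the
exact null score distribution on that lattice is computed by dynamic
programming over positions (the FIMO approach), giving
`p(s) = P(score >= s)` without approximation. The scanner sums the same
lattice scores, so table lookups are exact and the table agrees perfectly
with exhaustive word enumeration (verified up to width 8 in the tests).
Windows containing non-ACGT characters are skipped; hits are reported on
the forward strand at a p-value threshold of 1e-4 by default and 1e-6 for
genome-wide screens.

Enrichment per transcription factor is a 2×2 association test —
motif-positive versus motif-negative bins, differential
(|Diff/Sum| > 0.2) versus background — using the 1-df chi-square without
continuity correction (Yates available by flag); a degenerate margin
yields chi-square 0 rather than an undefined value. Both an uncorrected
α = 0.05 call and a Bonferroni-corrected call across the tested TFs are
reported, since the appropriate correction depends on the screen size.
The background bin set can be either all covered bins or shuffled
coordinates (`shuffle_intervals()`, a uniform non-overlapping relocation
null); the pipeline uses covered bins and records the choice.

## Peak classes and flank asymmetry

Binding-site peaks are partitioned by content: repeat-free motifs (RFM:
motif hit, no repeat overlap), motif-free repeats (MFR: repeat overlap, no
motif), `mixed`, and `neither`; RFM and MFR are exclusive by construction
and `mixed` peaks are excluded from their contrasts. Peaks are unstranded,
so "upstream/downstream" are genome-coordinate left/right and the center
is the interval midpoint. Flank windows are anchored at the peak edges
(`[start-flank, start)` and `[end, end+flank)`) so they never overlap the
peak; reads are assigned to 200 bp profile windows by midpoint, the
per-peak flank summary is the *sum* of window signals (the alternative
summary, the mean, differs only by a constant factor), and asymmetry is the
signed difference upstream − downstream. Peaks too close to a chromosome
end are flagged and excluded from asymmetry statistics. The CT-versus-KD
Pearson r² of per-peak asymmetries, per class, is the readout: a
knockdown that re-randomizes which flank of a motif-driven site is
methylated shows low r² at RFM against high r² at MFR.

## Allelic imbalance and parent of origin

At SNP sites, reads carrying the reference or alternate base are counted
per sample; bases matching neither allele are tallied separately and
excluded. Sites need 5 informative reads in each sample. AIM is the
Diff/Sum of allele counts; the source convention does not fix the order,
so `(ref − alt)` is the default with the mirrored `(alt − ref)` available
and the choice recorded on the result. At loci where both parents are
homozygous for different alleles the child is an obligate heterozygote and
every read's parent of origin is known; relabeling ref/alt as
paternal/maternal gives `(pat − mat)/(pat + mat)`. Values in the closed
interval [−0.5, +0.5] are biallelic; beyond it, a parental bias. The five
categories (stable biallelic, stable monoallelic, loss, gain, flip) are
exhaustive and mutually exclusive by construction of the sign pattern, and
relabeling maternal↔paternal swaps biases without changing category
counts.

## The synthetic data generator

The generator emulates the statistical structure the analysis assumes, at
bin resolution — MeDIP capture depends on local methylcytosine density, so
a per-bin, per-allele capture probability is the minimal faithful model.
Reads are single-end, fixed 150 bp, placed uniformly inside their source
bin so fragment-length variation collapses to one length for test
determinism.

Design choices that were genuinely open:

* **Baseline with domain structure.** Per-bin baselines are uniform draws
  on [0.05, 0.15] multiplied by a per-10 kb-domain factor on [0.5, 2].
  Real methylomes covary over multi-kilobase domains; without this, coarse
  bins would share no signal and the characteristic high 10 kb / low
  0.2 kb correlation contrast would not exist in the simulation.
* **Exchangeable stochastic flips.** A flipped bin's two levels
  `(m, m*f)`, `f` uniform on [1.25, 2], are assigned to (CT, KD) in random
  order. Modifying only KD would be asymmetric in the sampling tail: the
  lower-rate sample yields zero counts more often, biasing extreme
  Diff/Sum values toward losses. The exchangeable form makes GoM and LoM
  exactly symmetric at every magnitude, which is what a direction-free
  stochastic change means. The fold ceiling of 2 keeps stochastic
  magnitudes below ~1/3 so the deterministic band is separable.
* **Deterministic component.** Planted TFBS bins (default 50) carry an
  embedded motif consensus and a +0.4 methylation-probability shift in KD,
  which lands them at Diff/Sum ≈ 0.4–0.9 — above the stochastic band, so
  they depress entropy where they land and are recoverable by enrichment.
* **Peaks and flanks.** RFM peaks carry a motif and no repeat; MFR peaks a
  repeat annotation and no motif. Every peak gets a +0.3 methylation
  increment on one randomly chosen 10 kb flank; the chosen side is fixed
  between conditions except at RFM, where KD re-draws it independently
  (configurable). Planting asymmetry at both classes is what makes the
  class contrast well defined: MFR asymmetry stays correlated between
  conditions while RFM asymmetry decorrelates.
* **SNP states.** One heterozygous SNP per chosen bin at the bin center,
  parents homozygous for different alleles. Categories are drawn
  independently per locus (the analysis treats loci independently) with
  defaults 20% stable monoallelic, 15% gain, 15% loss, 10% flip, the rest
  stable biallelic; a methylated allele sits at probability 0.3, a silent
  one at 0.01. SNP bins keep their planted state and are exempt from
  flips and shifts so the planted categories remain exact ground truth.

The default problem size — two chromosomes of 350 kb (3,500 bins), 80,000
reads per condition, averaging ~23 reads per bin — was chosen so that
binomial noise in per-magnitude-bin entropy estimates is small relative to
the planted effects while a full 10-seed recovery suite remains quick to
run; the acceptance tests state their conditions in these units.

What the generator does *not* emulate: sequencing errors, PCR duplicates,
fragment-length variation, bisulfite chemistry, chromatin context, linkage
between neighboring SNPs, and cell-to-cell heterogeneity within a sample.
Passing recovery tests therefore demonstrate that the statistics identify
the structures they are defined on, not that real libraries are free of
the artifacts the generator omits.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere (BED convention); strand is
  ignored for coverage, as MeDIP is strand-agnostic.
* Diff/Sum of exactly 0 is neither GoM nor LoM.
* Histogram centers are decimal-rounded so bin lookups are exact.
* The PWM score lattice (0.01 log2-odds) bounds the p-value discretization
  error; the scanner and table share the lattice, so thresholding is
  self-consistent.
* Identical samples in the PCA have no between-sample variance; the single
  informative dimension is reported as fraction 1 by convention and the
  scores are zero. An all-zero matrix is an error.
* Degenerate (constant) count vectors make correlation undefined; they are
  reported as `NA`, never imputed.
* Chi-square tables with an empty margin report no association
  (chi-square 0), and expected cells below 1 set a `low_count` flag.

## Known limitations

The KS p-value on histograms is approximate by construction (documented
above). The per-TF enrichment treats bins as independent, ignoring spatial
autocorrelation of methylation. Flank profiles assign reads by midpoint,
which undercounts reads straddling window edges by at most one window.
The allele-count model consumes per-read base observations; it does not
re-call variants from raw pileups with base-quality models, and haplotype
phasing beyond obligate-heterozygous loci is out of scope.
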