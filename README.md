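# stochmeth

Bin-level analysis of stochastic cytosine-methylation change from
MeDIP-seq, for epigenomics researchers comparing a control (CT) and a
perturbed (KD, e.g. an RNAi knockdown) sample. The package quantifies how
much of a genome-wide methylation disturbance is random gain/loss versus a
directional, sequence-targeted change, and resolves allele-specific
methylation shifts down to parent of origin. A synthetic diploid MeDIP
read generator with complete ground truth drives every stage, so the whole
pipeline is testable without sequencing data.

## The statistics at its core

For each 0.2 kb genomic bin with normalized MeDIP read counts
`(CT, KD)`, the change statistic is the bounded ratio

    Diff/Sum = (KD − CT) / (KD + CT)  ∈  [−1, 1]

computed for bins with at least 3 combined reads. A positive value is a
gain of methylation (GoM), a negative value a loss (LoM). The *expected*
distribution under disturbance-without-net-change is obtained by mirroring:
the frequency at ±b is replaced by the mean of the two; observed and
expected are compared by a Kolmogorov–Smirnov statistic over the
bin-ordered CDFs and by a signed mean-shift summary in Diff/Sum units.

Stochasticity is quantified per |Diff/Sum| magnitude bin as the binary
Shannon entropy of the GoM/LoM state,

    H = −p log2 p − (1 − p) log2 (1 − p),   p = #GoM / (#GoM + #LoM),

so an equal presence of regions in gain and loss gives H = 1 bit and an
exclusive presence gives H = 0: high entropy means random, direction-free
change; low entropy at large magnitudes flags deterministic targets.

Around that sit: FIMO-style PWM scanning with exact dynamic-programming
p-values and per-TF 2×2 chi-square enrichment of motif-positive bins among
differential bins (|Diff/Sum| > 0.2); classification of binding-site peaks
into repeat-free motifs (RFM) versus motif-free repeats (MFR) with 10 kb
flank-asymmetry correlation between conditions; and allelic imbalance in
methylation (AIM), the Diff/Sum of reference/alternate allele counts at
heterozygous SNPs (coverage ≥ 5 per sample), classified at obligate
heterozygous loci into five parent-of-origin categories (stable biallelic,
stable monoallelic, loss, gain, allelic flip) with a ±0.5 bias threshold.

## Worked example

```r
library(stochmeth)

res <- run_pipeline(pipeline_config(seed = 1))

res$comparison
#> Observed vs mirrored-expected Diff/Sum comparison
#>   mean shift (Diff/Sum units): -0.0033
#>   mean frequency difference:   0
#>   KS D = 0.0084, p = 1 (over 21 histogram bins)
```

The simulated knockdown disturbs methylation symmetrically, so the observed
Diff/Sum distribution is statistically indistinguishable from its mirrored
expectation (no net methylation change) and the entropy profile stays near
1 bit at every change magnitude:

```r
head(res$entropy[res$entropy$n >= 50, ], 4)
#>   magnitude n_gom n_lom n_total     n p_gom entropy
#> 1       0     194   227     605   421 0.461   0.996
#> 2       0.1   525   534    1059  1059 0.496   1.000
#> 3       0.2   330   355     685   685 0.482   0.999
#> 4       0.3   175   204     379   379 0.462   0.996
```

The planted transcription factor is recovered as the top enrichment hit in
differential bins (its motif-positive bins occur at 3.8% of differential
bins against a 2.4% background; chi² = 16.6), and the flank-asymmetry
contrast separates peak classes: re-randomizing the asymmetric flank side
of RFM peaks in the knockdown collapses their CT/KD asymmetry correlation
while MFR peaks stay correlated:

```r
res$asymmetry
#>   site_class     n     r r_squared
#> 1 MFR           10 0.998     0.997
#> 2 RFM           10 0.290     0.084

table(res$poo$category)
#>        allelic_flip    biallelic_stable gain_of_monoallelic
#>                  27                 126                  52
#> loss_of_monoallelic  monoallelic_stable
#>                  47                  47
```

The parent-of-origin table recovers the planted allelic category mix
(40% biallelic, 20% stable monoallelic, 15% gain, 15% loss, 10% flip over
300 SNPs). Plot helpers (`plot_diffsum_distribution()`,
`plot_entropy_profile()`, `plot_flank_profile()`, `plot_aim_scatter()`,
`autoplot()` on the PCA object) render the standard figures, and `tidy()` /
`glance()` methods expose results as tibbles.

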