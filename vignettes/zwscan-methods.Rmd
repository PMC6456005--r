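---
title: "Methods: coverage-based Z discovery, young ZW strata, and dosage compensation"
author: "zwscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based Z discovery, young ZW strata, and dosage compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwscan)
```

## The problem

In a female-heterogametic (ZW) species, females carry one Z and one W while
males carry two Z copies. Two genomic signatures follow. Where the W has
degenerated and no longer aligns to the Z ("Z-specific" regions), a female
DNA library covers those scaffolds at half the male dose, so the per-scaffold
log2(female:male) depth ratio sits near −1 while autosomes sit near 0. Where
Z and W diverged only recently, both haplotypes co-assemble into one scaffold
at equal depth in both sexes; the only trace of sex linkage is allelic: sites
fixed between Z and W are heterozygous in every female sample and homozygous
in every male sample. `zwscan` implements both detectors, a reverse-polarity
false-positive control for each, an expression module that asks whether
Z-specific genes are dosage compensated, and a qPCR ΔΔCq module for
locus-level copy-number verification.

## Coverage-based assignment (`assign_coverage`)

Scaffolds are first filtered: length strictly greater than `min_len`
(default 5,000 bp; 1, 2 and 10 kb are supported for sensitivity checks),
depth in the homogametic reference sex (male for ZW) at least ¼ of that
sex's genome-wide average, and depth in each sex at most 4× that sex's
average. The "average" is the length-weighted mean by default; an unweighted
median is available via `center = "median"` because either summary is
defensible for anchoring the ¼/4× rules, and on clean data they nearly
coincide.

For retained scaffolds, the statistic is `log2(depth_F / depth_M)` centered
on its unweighted median across scaffolds. Centering makes every window a
*relative* window: adding a constant to all ratios (for example, a global
library-size imbalance) changes nothing. Windows, as offsets from the
median:

| zone      | window              | boundary handling |
|-----------|---------------------|-------------------|
| Z         | [−2, −0.5]          | both ends inclusive |
| autosome  | (−0.5, +2)          | both ends exclusive |
| pseudo-X  | [+0.5, +2]          | inclusive |

The −0.5 cutoff is the equidistant point between the expected autosomal peak
(0) and the Z-specific peak (−1). The shared boundary at −0.5 is assigned to
Z so that exact-boundary values — measure-zero in real data but possible in
tests — are deterministic. Three stricter presets (`"t1"`–`"t3"`, Z ceiling
−0.6/−0.7/−0.8 with autosome floor −0.4/−0.3/−0.2) shrink the Z window
monotonically and are used to show conclusions do not hinge on the cutoff.
The pseudo-X window is the mirror image of the Z window: a ZW species cannot
have a differentiated X, so scaffolds landing there estimate the
false-positive rate of the whole procedure. Scaffolds below the zone floor
or above the ceiling stay `unassigned`; scaffolds removed by the filters are
reported as `filtered`, so the output partitions the input exactly.

## Young, coverage-undifferentiated ZW strata (`reverse_control`)

SNP input is a biallelic site table (VCF 4.2 with per-sample `AD`) from four
female and four male pooled RNA samples plus one DNA individual per sex.
Filters: indels and multiallelic records dropped; site quality strictly
above 20; any sample with fewer than 10 reads at a site is masked at that
site. Genotypes are hard-called from allele fractions: homozygous at
≤ 0.15 / ≥ 0.85, heterozygous only when the minor fraction strictly exceeds
0.30. The band (0.15, 0.30] is deliberately a `no_call`: pooled samples
inflate spurious heterozygotes, and the stricter 30% rule is applied *on
top of* the 0.15/0.85 caller thresholds rather than re-interpreting the band
as a genotype.

A site is ZW-consistent when all four female pools are heterozygous and all
four male pools homozygous; one missing or ambiguous call makes it
`unassessable` (it counts in neither numerator nor denominator). Scanning
only scaffolds the coverage pipeline called autosomal, a scaffold is flagged
as putative young stratum when it has at least 10 classified SNPs of which
at least 20% are ZW-consistent. Flagged-scaffold SNPs are then re-genotyped
in the two DNA individuals (same depth and fraction rules; "sufficient
coverage" is taken as the same 10-read rule) and the DNA confirmation rate
is compared with the genome-wide background rate by a two-proportion
chi-square with Yates continuity correction (`proportion_chisq`, hand-coded
and cross-checked against `prop.test` in the test suite). As printed in the
source analyses this comparison treats the flagged subset and the full set
as independent samples even though one contains the other; `zwscan`
reproduces that convention. The entire analysis is then repeated with the
sexes' roles swapped (XY polarity). Since XY-consistent patterns cannot be
real in a ZW species, the reverse branch measures the noise floor, and the
concentration of consistent SNPs on flagged scaffolds is compared between
polarities with the same chi-square.

## Dosage compensation (`dosage_report`)

Expression is RPKM (`count · 10⁹ / (length · library_size)`, library size =
column sum), quantile-normalized within each tissue across all four samples
(both sexes jointly — the normalization target is the tissue, not the sex).
A gene is "expressed" in a tissue when all four samples have RPKM ≥ cutoff
(default 1; 0, 2, 5 supported). Replicates are then averaged and a second
quantile normalization is applied across the two per-sex columns.
Comparisons are two-sided Wilcoxon rank-sum tests (exact for small untied
samples, tie-corrected normal approximation otherwise): female vs male on
Z genes, on autosomal genes, Z vs autosome within each sex, and the
per-gene log2(F/M) ratios of Z vs autosomal genes. Because the RPKM ≥ 1
filter precedes ratio formation, no pseudocount is needed.

One consequence of quantile normalization worth knowing: when a sizeable
fraction of the transcriptome is Z-linked and truly uncompensated, forcing
the female and male columns onto a common distribution compresses the
observed Z deficit toward 1. With Z at ~10% of transcripts a true 2-fold
deficit is observed as a median F:M near 0.52–0.56 rather than 0.50; the
statistical discrimination is untouched. This is a property of the
published normalization choice, not of this implementation.

Sex-specific transcripts use the strict rule RPKM < 0.1 in both replicates
of one sex and > 1 in both replicates of the other. Sex-*biased* transcripts
come from a deliberately lightweight stand-in, not DESeq2: counts are
normalized by median-of-ratios size factors, log2-transformed with a 0.5
pseudocount, and tested with an empirical-Bayes moderated t-test (limma,
`trend = TRUE`), BH-adjusted at α = 0.05. A pure rank test was rejected at
the design stage: with two replicates per sex the smallest achievable
two-sided rank-sum p-value is 1/3, so no gene could ever clear an adjusted
0.05 — variance moderation across genes is the minimal machinery that makes
a 2 vs 2 design testable. Outputs label these calls as coming from the
stand-in. Enrichment questions (overlap of sex-biased genes between
tissues; counts of sex-biased genes on Z vs autosomes) use two-sided
Fisher exact tests.

## qPCR copy-number verification (`analyze_qpcr`)

For genomic DNA, a Z-specific locus has two template copies in males and
one in females, so at 100% amplification efficiency the female target
crosses threshold one cycle later. Per individual, the reference Cq is the
mean over the autosomal normalizer genes; ΔCq = Cq(target) − Cq(reference);
the calibrator is the female group's mean ΔCq (the choice of calibrator
cancels in the male:female ratio, so this convention only fixes female
folds at ~1); fold = 2^(−ΔΔCq). Efficiency is fixed at 2.0 per cycle — no
dilution-series correction is modeled. The male:female fold is called
`Z_linked` in [1.5, 3.0], `autosomal` in [0.67, 1.33], otherwise
`indeterminate`; the windows are judgment calls bracketing the 2× and 1×
expectations with a deliberate gap between them.

## The synthetic-data generator (`sim_config` and friends)

The generator produces every input the analysis consumes, with known truth:
scaffold classes (autosomal / Z-specific / young-Z), per-sex coverage,
pooled RNA and individual DNA genotypes as VCF, an RNA-seq count matrix for
2 tissues × 2 sexes × 2 replicates, and qPCR Cq tables. Defaults emulate
the target study design: 28× female and 30× male coverage, four pools of
five individuals per sex, DNA individuals from a line inbred by six
generations of full-sib mating.

Choices that matter:

* **Coverage noise.** The `depth_dispersion` log-normal factor (CV 0.2 by
  default) is *shared* between the sexes: it models scaffold-level coverage
  bias (GC, mappability, repeats), which affects both libraries alike and
  largely cancels in the F:M ratio — as it does in real resequencing data,
  where per-scaffold mean depths scatter far more than their between-sample
  ratios. Each sex additionally gets independent read-counting noise with
  CV `1/sqrt(depth · length / 100)` (the sampling error of a mean depth
  built from ~100 bp reads), which is what actually spreads the log2 ratio.
  Modeling the full dispersion as sex-independent would make the ratio
  useless at CV 0.2 and would not resemble real libraries.
* **Pooled genotypes.** A pool of *n* diploids draws its allele count
  binomially from the population frequency (uniform 0.05–0.5 for ordinary
  polymorphism); read support is Poisson depth with binomial allele
  sampling. Young-Z scaffolds carry fixed ZW differences (female pools at
  allele fraction 0.5, male pools at 0) on a configurable fraction of their
  sites — 0.5 by default, so the ≥ 20% consistency rule is exercised with a
  margin rather than trivially. `genotyping_error` replaces a sample's
  true allele state by a flipped one; `dna_missing_rate` zeroes DNA
  coverage at a site.
* **Inbreeding.** Residual DNA heterozygosity is scaled by (1 − F) with F
  from the full-sib recurrence `F_t = (1 + 2F_{t−1} + F_{t−2})/4`; six
  generations give F = 0.734375. Descriptions of such lines sometimes round
  this to "80% reduction in heterozygosity"; the recurrence value ~73% is
  used, and the discrepancy is noted rather than resolved.
* **Counts.** Log-normal baseline expression, mild log-normal tissue
  effect, expected counts proportional to expression × length scaled to the
  library size, gamma-Poisson overdispersion. Under
  `compensation_scenario = "none"` female Z expression is halved (the dose
  is passed straight to mRNA); `"full"` leaves it equal. Truly sex-biased
  transcripts are multiplied by `sexbias_fold` in the favoured sex.
* **Determinism.** Every artifact derives its own RNG stream from the
  master seed (fixed small offsets), so regenerating one file never
  perturbs another and identical configurations are byte-identical.

What the generator does *not* emulate: read-level artifacts (no FASTQ, no
mapping bias), indels and multiallelic sites, linkage and recombination
structure, GC-dependent expression bias, and assembly errors such as
chimeric scaffolds. Passing the recovery tests therefore demonstrates that
the statistical machinery is correct under the stated generative model, not
that real libraries are free of those artifacts.

## Problem sizes and test design

The validation suite runs at desk scale, chosen to keep the full suite
under a minute while leaving the conclusions stable across seeds: coverage
recovery uses 10 seeds × 500 scaffolds (expecting Z precision and recall
≥ 0.95 at dispersion 0.2); stratum recovery uses 10 seeds × 120 scaffolds
of 10–40 kb (≥ 90% of young-Z scaffolds flagged in aggregate, at most one
autosomal false positive per genome, a silent reverse control); dosage
discrimination uses 10 seeds per scenario with ~1,120 scaffolds and ≥ 300
expressed Z genes (full compensation: F-vs-M on Z non-significant in
≥ 9/10 seeds; none: p < 0.01 in 10/10 with median Z F:M within 0.15 of
0.5, the band reflecting the quantile-normalization compression discussed
above). Statistical primitives are verified against independent oracles:
the chi-square against `prop.test` on 1,000 random tables, Wilcoxon against
exhaustive permutation enumeration, Fisher against hypergeometric
enumeration, BH against hand-computed step-up examples.

## Known limitations

* Genotype calling is hard-threshold, not likelihood-based; sites near the
  thresholds are discarded rather than weighted.
* The DE stand-in shares information across genes only through variance
  moderation; it does not model count dispersion as a negative binomial
  and should not be quoted as DESeq2 output.
* The young-stratum detector needs ≥ 10 classified SNPs per scaffold, so
  short or SNP-poor scaffolds are invisible to it regardless of their true
  state.
* With very small retained-scaffold sets the median anchor is noisy; the
  pipeline does not currently propagate that uncertainty into the zone
  calls.

## A worked example

```{r example, eval = FALSE}
out <- tempfile("zwscan_")
summary <- run_pipeline(list(
  simulate = list(n_autosomal_scaffolds = 100, n_z_scaffolds = 20,
                  n_youngz_scaffolds = 10, seed = 7)
), out)
str(summary$scaffold_classes)
summary$young_stratum$comparison_chi2
```
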