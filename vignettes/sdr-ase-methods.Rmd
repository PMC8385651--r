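---
title: "Detecting sex-associated allele-specific expression in a sex-determining region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-associated allele-specific expression in a sex-determining region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrase)
library(dplyr)
```

## The model

`sdrase` detects two genomic signatures of a young XY-type sex-determining
region (SDR):

1. **Sex-associated allele-specific expression (ASE).** An individual that
   is heterozygous at a site shows a genomic alt-allele fraction near 0.5.
   If the gene's Y-haplotype copy is transcriptionally silenced, every
   heterozygous site in that gene shows a cDNA major-allele fraction near 1
   — but only in males, because only males carry a Y haplotype. The
   pipeline formalizes this contrast site by site, aggregates it to a
   gene × individual call with a cross-tissue consistency requirement, and
   tests sex association across a cohort with a one-sided Fisher exact
   test.
2. **Male hemizygosity.** Y-specific sequence yields half-depth coverage in
   males (one haplotype) and zero coverage in females. Binned, normalized
   WGS depth over the SDR window separates these states cleanly at typical
   short-read depths.

The package treats per-site allele depths as the sufficient statistic of
the sequencing experiment: read trimming, alignment and variant discovery
happen upstream, and the pipeline starts from a VCF with per-sample
`GT:AD:DP` fields, binned coverage tables, and a gene × library count
matrix.

## Tunable parameters

All thresholds are exposed in `default_pipeline_config()` and echoed into
every run's output directory.

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_phred` | 15 | Phred | variant candidates below this site quality are dropped |
| `dna_min_depth` | 20 | reads | below this a genotype is undetermined; robust at both WGS (~20×) and amplicon (~2000×) depths |
| `het_band` | [0.2, 0.8] | fraction | operationalizes a genomic allele frequency "about one half"; wide enough for binomial noise at depth 20, narrow enough to exclude 10% contamination |
| `error_rate` | 0.01 | probability | exact binomial test of the minor count under homozygosity |
| `mono_threshold` | 0.9 | fraction | cDNA major-allele fraction counted as monoallelic; a transcript frequency "close to one" |
| `rna_min_depth` | 20 | reads | minimum informative cDNA depth per site |
| `min_sites` | 2 | sites | a gene call needs at least two informative heterozygous sites |
| `site_agreement` | 0.8 | fraction | per-tissue majority required for a consistent gene call |
| `alpha` | 0.05 | — | label threshold for the exact test; Bonferroni optional (`correction`), off by default for a three-gene panel |
| `male_min` / `female_max` | 0.3 / 0.1 | normalized depth | separate the 0.5-copy male signal and 0-copy female signal from noise at ≥ 15× |
| `min_run` | 2 | bins | suppresses single-bin noise in the hemizygosity scan |
| `expressed_min` | 0.1 | normalized depth | mean RNA depth over a region counted as "expressed" |
| `min_cpm` / `min_fold` | 8 / 2 | CPM / fold | the descriptive differential-expression screen |
| `min_mean_cpm` | 16 | CPM | gene filter for the Spearman distance matrix |

Genotype calls use a band plus an exact homozygosity test rather than a
likelihood model: at the two depth regimes the pipeline sees (tens vs
thousands of reads), the band is what keeps behaviour comparable, while the
binomial test prevents deep amplicon data from calling a 1%-error
homozygote "heterozygous" or a 15%-fraction site "homozygous".

## What the synthetic cohort emulates

`truth_config()` fixes the generative design; `simulate_cohort()` draws
from it deterministically given a seed.

* **Design**: one male (18× WGS) and one female (26× WGS), each with bulk
  RNA-seq of leaves, catkin axes and flowers (six libraries); and an
  amplicon panel over 10 males + 10 females sampled as DNA from leaves plus
  cDNA from the three tissues — 80 samples. The WGS depths, cohort sizes and tissue
  sets are the design constants the generator declares.
* **Gene truth**: the five annotated SDR genes, with TCP, CLC and MET1
  transcribed and NB-ARC and the unannotated gene silent. The CLC-like gene
  carries `y_fraction_male = 0` (complete Y-allele silencing); every other
  expressed gene is biallelic in both sexes (`0.5`).
* **Read model**: per-site total depth is Poisson; the alt count is
  beta-binomial with mean `f(1−e) + (1−f)e` (true fraction `f`, sequencing
  error `e = 0.005`) and intra-class correlation `rho = 0.02`. The error
  rate and overdispersion are declared defaults chosen as typical for
  Illumina amplicon data; `rho = 0` recovers pure binomial sampling.
* **Coverage**: per-bin depth is drawn as Poisson base counts over the
  200-bp bin (`Poisson(depth × width)/width`), the right dispersion for a
  binned mean rather than a single-site draw. Two Y-specific intervals
  (4 kb and 2 kb, bin-aligned, intergenic) are planted: male expectation
  drops to one-haplotype depth, female to zero, and no transcription is
  placed over them.
* **Counts**: 2,000 background genes with log-normal baseline rates and
  negative-binomial noise; 3% of genes get a sex effect in leaves and 15%
  in the generative tissues (fourfold, random direction), reproducing the
  observed pattern that male and female leaves differ far less than male
  and female flowers. These fractions are package choices on the same
  order as typical sexed-tissue DEG counts relative to a transcriptome.
* **Seeding**: each (sample, material, tissue) stream derives its own seed
  from the global one by stable string hashing, so enlarging the cohort
  does not perturb existing samples — a property the test suite asserts.

What the generator does **not** emulate: mapping bias toward the reference
allele, index hopping and sample cross-talk in amplicon pools, isoform
structure, PCR duplicate structure, and real linkage between neighbouring
sites (sites are drawn independently within a gene). Passing tests
therefore demonstrate the correctness of the *inference logic* under the
declared noise model, not robustness to alignment artefacts; with real
data, reference-bias checks remain the user's responsibility.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; GFF3 and VCF convert
  at the boundary, BED is native. The conversion pair is involutive and
  tested. The final partial bin of an interval is kept truncated rather
  than dropped.
* **Chromosome labels are opaque.** The reference assembly places this SDR
  on chromosome 18 while genetic maps put it on chromosome 19; the package
  records coordinates as given and attaches no meaning to the label.
* **Multi-allelic sites** decompose into ref-vs-each-alt observations;
  third alleles never enter a fraction.
* **Phase is not required** for a monoallelic gene call: each site must be
  monoallelic for *some* allele, without requiring the dominant alleles to
  lie on one haplotype. Real phase is unknown; the simulator's truth tables
  enable a stricter phased check if wanted.
* **Direction of the exact test** follows the sex with the larger
  monoallelic proportion, because direction is part of the claim being
  tested; undetermined individuals are excluded from the 2×2 table rather
  than imputed. With all individuals undetermined the p-value is undefined
  and the label is `none`.
* **TMM** factors come from edgeR (`calcNormFactors`), the reference
  implementation of the trimmed-mean-of-M-values method; CPM, the
  fold-change screen and the Spearman distance are computed in-package. A
  pseudo-count of 0.5 per CPM value stabilizes fold changes at zero counts.
  The 2-fold screen runs on TMM-adjusted CPM (normalization is stated
  before the screen, so adjusted values are the natural reading); note
  Spearman correlations themselves are invariant to per-library scaling,
  so TMM affects only the distance matrix's gene filter.
* **Hemizygosity normalization** divides by the sample's median bin depth;
  the scan window is overwhelmingly diploid, making the median a robust
  single-copy reference. For sparse RNA tracks the median over non-zero
  bins (or an explicit reference) is used instead, since the all-bin
  median is zero.
* **Gene spans are opaque**: the annotated coordinates may or may not
  include UTRs; the package treats them as whole-gene intervals and plants
  heterozygous sites uniformly within them.

## Problem sizes

The test suite runs the full amplicon design (20 plants, 6 sites per gene,
depth 2,000) end to end in single seconds; planted-truth recovery is
checked over 40 seeds, the null false-positive rate of the association test
over 500 replicate cohorts, and the heterozygote caller over 2,000
simulated 30× sites — sizes chosen to give the relevant Monte-Carlo
estimates sub-percent standard errors while keeping the default test run
fast on one core.

## Known limitations

* The genotype caller genotypes sites already present in the input VCF; it
  performs no variant discovery.
* The DEG screen is a descriptive CPM/fold filter, not a dispersion-aware
  test; it reports no p-values and is not a substitute for a count-model
  analysis when replicates exist.
* The hemizygosity scan resolves presence/absence at bin resolution (200 bp
  by default); it does not resolve breakpoints or classify repeat content.
* Cross-tissue consistency treats tissues symmetrically; genuinely
  tissue-restricted ASE would be reported as undetermined rather than
  called per tissue (the per-tissue site table is available for that).
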