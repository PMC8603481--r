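---
title: "Detecting selective sweeps with coalescent-calibrated diversity scans"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with coalescent-calibrated diversity scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem

A hard selective sweep drags linked variation to fixation and leaves a
localized trough of genetic diversity. `sweepscan` detects such troughs in
resequenced populations (the motivating system is wild house mouse
populations, but nothing is mouse-specific) by computing three windowed
diversity statistics from a population VCF, calibrating one-tailed
significance thresholds against neutral coalescent simulations under a
population-specific demographic model, collapsing outlier windows into
candidate regions, removing false positives caused by segregating
copy-number variation, and finally asking whether the genes in the surviving
regions are enriched for externally defined gene sets (disease genes, GWAS
genes) or for differential expression.

# The statistics

All statistics are computed in 20-kb windows sliding by 10 kb (defaults;
both are tunable in bp). Windows with fewer than 50 SNP records are excluded
and also break the adjacency used to merge candidate windows.

**Pool heterozygosity.** For the SNP records of a window with per-site major
and minor allele counts,
$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
            {(\Sigma n_{MAJ}+\Sigma n_{MIN})^2},$$
bounded by $[0, 0.5]$. $H_p$ is a *pool* statistic: it needs only summed
allele counts, so sites with missing genotypes still contribute their
genotyped alleles, and records that are fixed for the alternate allele
within the population (ubiquitous in callsets made against a diverged
reference genome) contribute major-allele mass with zero minor mass. A
swept window therefore has $H_p \approx 0$ rather than no data — this is
deliberate and is what makes completed sweeps visible to the scan at all
(see *Reference divergence* below).

**Nucleotide diversity.** The unbiased per-site estimator summed over
complete (zero-missing) sites and divided by the full window length $L$:
$\pi = \sum_i 2 c_i (n - c_i) / (n(n-1)) / L$. Using the full $L$ rather
than callable sites is a stated limitation: no callability mask is modeled.

**Tajima's D.** The standard normalized difference between $\bar k$ (mean
pairwise differences) and $S/a_1$, using the 1989 constants with the
constant $n$ guaranteed by restricting to complete sites. $D$ is undefined
when $S = 0$.

Sites with any missing genotype are excluded from $\pi$, $S$ and $D$ so
that $n$ is constant within a population (the D constants require it); a
per-site varying-$n$ alternative was considered and rejected for that
reason. The `nSNP` filter quantity counts all admitted records, i.e. what a
VCF SNP tally reports.

**Normalization.** Each statistic is Z-scored over the retained windows of
its population using the population (denominator-$N$) standard deviation.
The convention is arbitrary but fixed and tested; thresholds are applied on
the raw scale, so the choice only affects plotting.

# The neutral null

Demographic history alone can produce diversity troughs. The null model is
a single-population coalescent with piecewise-constant size history in ms
dialect: `-t <theta>` plus `-eN <t> <x>` events (time in units of $4N_0$
generations, size as a multiple of $N_0$). Events may be written in any
order, as ms accepts; they are sorted internally for simulation and
preserved verbatim for serialization. The simulator draws exponential
coalescence times at rate $k(k-1)/x$, places Poisson($\theta_w T_{tot}$)
infinite-sites mutations on the genealogy, and was cross-checked against
msprime under the same size history. There is no recombination, matching
the commands (no `-r` flag); a no-recombination null has *wider* window
statistic distributions, which makes the extreme-value threshold more
conservative.

**Theta rescaling.** Printed `-t` values refer to the reference locus
length they were estimated on (300-kb putatively neutral regions, the
package default for `refLength`); simulations of a 20-kb window use
$\theta \cdot 20/300$, since $\theta$ scales linearly with locus length.
The per-replicate locus length of the original analyses is not stated, so
this rescaling is an interpretation, recorded here as the package's choice.

**Thresholds.** 10,000 simulated windows per population; the significance
threshold of each statistic is the *minimum* simulated value — the extreme
value in the one-tailed direction a sweep pushes each statistic — and an
observed window is flagged only when strictly below it. This is the most
conservative reading of an extreme-value threshold: with 10,000 draws,
essentially only windows with near-zero diversity can ever be flagged.

**Ascertainment matching.** Observed windows contain reference-fixed
records that dilute $H_p$; coalescent simulations naturally contain none.
`buildNull()` therefore accepts `fixedPerWindow`, the mean density of
zero-minor records per window, which the pipeline estimates from the
observed VariantTable (`estimateFixedSiteRate()`) and injects into each
simulated window before computing $H_p$. Without this the simulated
$H_p$ null would sit systematically above the observed distribution and
the minimum rule would miscalibrate. This calibration step is the
package's own design; it has no analogue in the original analysis.

**Sample-size choice.** Simulations use $n = 2\times$ the population's
diploid count, configurable. Per-simulation RNG streams derive from the
master seed by counter, so the first $k$ simulations of a run are identical
regardless of how many follow — thresholds can only move down as
simulations are added.

# Region calling

Candidate windows are those flagged by $H_p$ *and* by at least one of
$\pi$ or $D$ (the default requires co-support in the same window; a
region-level mode is provided because the source phrasing is ambiguous).
Candidates that overlap or are book-ended merge into regions; windows
excluded by the SNP-count filter break adjacency, since absent evidence
should not bridge two candidate runs. Genes attach to regions by $\ge$1 bp
overlap.

# The copy-number filter

A segregating deletion reduces apparent diversity and halves carrier read
depth, so diversity troughs over deletions are artifacts, not sweeps. The
filter: per-sample read depth in 1-kb windows is GC-corrected by
median-ratio within 1-percentage-point GC bins (bins with fewer than 100
windows fall back to no correction), standardized by the genome-wide *mean*
corrected depth to copy-number estimates ($CN = 2\,d/\bar d$), rounded to
integer calls with exact half-points resolved downward (the conservative,
masking direction). The diploid mask is the intersection of CN = 2 calls
across all samples; candidate regions overlapping its complement are
discarded (any overlap by default; a fraction threshold is exposed).

The mean (not median) baseline follows the "genome-wide average" wording of
the method it reproduces. On a whole genome a CNV contaminates that mean
negligibly; on very small test genomes a large deletion can shift it by
several percent, which is why the bundled test scenarios use a 10-Mb
genome.

# Enrichment tests

**Region resampling.** The observed fraction (of regions overlapping a
qualifying gene, or of overlapped genes belonging to a set — both modes are
reported, since both phrasings occur in the source analyses) is compared
with 1000 random region sets, size-matched to the observed lengths,
uniformly placed, mutually non-overlapping, never clipped at chromosome
ends (rejection sampling, 1000 attempts per region before a hard error).
No assembly-gap track is excluded by default; an excluded-intervals input
exists for users who have one.

**DE subsampling.** For each tissue, the DE fraction of the selection genes
is compared with 10,000 random same-size gene draws from the tissue's
expression universe.

**Empirical p.** $p = \#\{\text{null} \ge \text{observed}\}/R$, the plain
proportion with no +1 correction, ties counting against rejection (the
source text says "greater than" but its own saturation behavior requires
$\ge$; the conservative reading is used). $p = 0$ is reported as
"< 1/R".

# The synthetic-data generator

Every pipeline stage is testable without downloads. The generator draws
neutral genomes tile-by-tile (20-kb tiles, independent — no linkage across
tiles, a deliberate desk-scale simplification that the window statistics,
which use no cross-window linkage, do not notice), pairs haplotypes into
diploids, and emits the exact formats the readers consume (VCF, GFF3,
bedGraph-like depth, TSV gene sets and DE tables) plus a JSON truth
manifest from which the dataset regenerates bit-for-bit.

Key modeling choices, fixed once:

* **Demography**: the bottleneck-then-expansion command of the Indian
  population (`-t 1230 -eN 0.369 0.407 -eN 0.233 0.640`), i.e. the
  population in which the motivating deletion artifact was described;
  $\theta$ rescaled by tile length / 300 kb.
* **Reference divergence** `d = 0.005`/bp: the REF allele is a diverged
  outgroup allele at Poisson($d L$) sites per tile, at which all population
  haplotypes carry ALT. Population VCFs called against a diverged reference
  (mouse data against C57BL/6J) are full of such fixed-ALT records; they
  keep swept windows above the 50-SNP filter and pin their $H_p$ at 0.
  Without them a complete sweep would have *no* VCF records and would be
  invisible to the scan — an unrealistic artifact of omitting the
  reference, not a property of real data.
* **Sweeps** are planted by replacing a fraction $f$ of haplotypes with
  copies of one template (completeness $f = 1$ is a completed hard sweep).
  Haplotype replacement produces exactly the diversity-trough signature the
  scan targets with controllable completeness; forward simulation with
  selection coefficients would add machinery without adding test power.
  All-reference sites are dropped afterwards; template-derived sites remain
  as fixed-ALT records.
* **Deletions**: each haplotype carries the deletion with probability $q$;
  heterozygous carriers appear homozygous for the retained haplotype's
  allele, samples with both copies deleted have missing genotypes, and
  carrier depth scales by $CN/2$ — genotype and depth channels share the
  same carriers by construction.
* **Depth**: shared per-window GC from Beta(42, 58); unimodal quadratic
  bias $\max(0.05,\,1 - 3(gc - 0.45)^2)$ normalized to 1 at its mode;
  observed read counts Poisson around
  $\text{coverage}\cdot L_w/150 \cdot \text{bias} \cdot CN/2$. Default
  coverage is 60×: a power analysis of the CN caller shows that at 30× the
  Poisson noise alone miscalls $\sim 5\times10^{-4}$ of sample-windows,
  enough to pepper the diploid mask with holes that the zero-tolerance
  discard rule would amplify into mass false discards; at 60× (~400 reads
  per window) the miscall rate is $\sim 10^{-6}$. No overdispersion knob in
  this version (documented extension point).
* **Gene annotation**: 600 genes on a 10-Mb genome, log-normal lengths
  (median 20 kb), 90% protein-coding; set membership Bernoulli($p_0$) with
  the odds multiplied by a configurable factor for genes overlapping a
  planted sweep (multiplier 1 is the calibration null). DE flags are
  generated the same way per tissue. The gene density is deliberately
  higher than a real mammalian genome so that enrichment tests on a 10-Mb
  toy genome have realistic gene counts per region set.

## What the generator does and does not emulate

It emulates: neutral coalescent variation under a bottleneck-then-expansion
history; localized diversity troughs from hard sweeps; deletions that
depress apparent diversity and halve carrier depth coherently; GC-dependent
depth bias; and controllable gene-set/DE enrichment among sweep genes. It
does **not** emulate recombination or linkage between tiles, callability
masks, genotyping error, overdispersed coverage, soft sweeps, or
cross-population site ascertainment. Passing tests therefore demonstrate
the pipeline's logic and calibration under the stated generative model, not
performance on real sequencing artifacts.

The last omission matters for one scenario: in the original data, a
high-frequency deletion masquerades as a sweep partly because the joint,
multi-population callset lists sites that are monomorphic within the
deleted population's surviving pool, crushing pooled $H_p$. A
single-population callset carries no such sites, and dropping
missing-genotype sites removes most of the rest of the signal: within this
package's scope the genotype channel of a 90% deletion only *sometimes*
(measured: 15-25% of seeds) drops below the extreme-value threshold, while
the depth channel flags it essentially always. The copy-number mask — not
the diversity scan — is the reliable defense against deletion artifacts
here, and every deletion locus that is called does get discarded by the
mask in the bundled experiments.

# Numerical and degenerate-input conventions

* $H_p$ of a window with no SNP records is missing; with records but zero
  summed minor counts it is exactly 0.
* $\pi$ of an empty window is 0 (no differences observed over $L$); $D$ is
  missing when $S = 0$ or the variance term vanishes.
* Windows shorter than the window size (chromosome ends) are kept and
  flagged `clipped`; the SNP-count filter usually removes them.
* Exact CN half-points round to the lower call; ties in major/minor
  orientation are irrelevant to the fold-invariant statistics.
* Empirical p ties count toward the null ($\ge$), the conservative side.
* All stages are pure functions of (inputs, config, seeds); reruns are
  byte-identical, and the dataset generator regenerates bit-for-bit from
  its manifest.

# Problem sizes used in the bundled experiments

The package's experiments run on 10-Mb genomes (5 × 2 Mb) with 20 diploid
samples, 10,000 null simulations per threshold set, 1000 region-resampling
replicates, 10,000 DE replicates, 20 seeds for scan-level experiments and
50–200 datasets for calibration/power — sizes chosen so the full suite
runs on a laptop while keeping every Monte Carlo comparison inside its
stated tolerance.

# A worked example

```{r example, eval = FALSE}
dir <- tempfile("sweepscan-demo")
generateDataset(dir,
    sweeps = data.frame(chrom = "chr1", start = 1000001, end = 1100000, f = 1),
    deletions = data.frame(chrom = "chr3", start = 1200001, end = 1400000,
                           q = 0.9),
    seed = 1)
cfg <- readPipelineConfig(file.path(dir, "config.yaml"))
runAll(cfg)
# candidate regions, CN-filtered catalog, enrichment table:
readLines(file.path(cfg$outdir, "synthpop.regions.retained.bed"))
read.delim(file.path(cfg$outdir, "synthpop.enrichment.tsv"))
```

# Known limitations

* Hard-sweep signatures only; soft sweeps and polygenic adaptation are out
  of scope by design, as are haplotype statistics (iHS, XP-EHH) and Fst.
* $\pi$ uses the full window length; regions with poor callability will
  have depressed $\pi$ for reasons unrelated to selection.
* The minimum-of-10,000 threshold is extremely conservative: partial
  sweeps (e.g. 90% completeness) generally do not reach it; the scan is
  tuned, like its source, to completed sweeps.
* The deletion false-positive mechanism is only partially reproducible
  from a single-population callset (see above); users with joint
  multi-population VCFs should still rely on the CN mask.
* No kinship-aware resampling in the enrichment tests.
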