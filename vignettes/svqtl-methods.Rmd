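---
title: "Methods: structural-variant QTL discovery in multiparental DH populations"
author: "svqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant QTL discovery in multiparental DH populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svqtl)
```

`svqtl` analyzes nested association-mapping (NAM) populations of doubled
haploid (DH) lines — several biparental crosses sharing one common elite
parent — to discover small structural variants (deletions and insertions,
30 bp and up) associated with a quantitative trait, here days to onset of
flowering (BBCH 61). This vignette explains the models behind each stage,
the defaults and why they were chosen, what the synthetic data generator
does and does not emulate, and the package's known limitations.

## The population and trait model

A DH line is one recombinant F1 gamete doubled to homozygosity, so every
locus is homozygous and segregates 1:1 within a cross. The generator
(`makeDHPopulation`) draws crossover counts per chromosome as
Poisson(map length in Morgans) with positions uniform on the cM scale —
the Haldane model, no interference. Interference changes crossover
spacing but not the 1:1 segregation or the expected recombination
fractions that the downstream statistics rely on, so the simplest model
consistent with a cM map was chosen. Founder haplotypes are i.i.d.
Bernoulli(0.5) per marker by default; with `blockCM > 0` each chromosome
is partitioned into ancestral blocks of that genetic length and every
founder carries one of two ancestral haplotypes per block. This is what
creates linkage disequilibrium at the founder level — without it, LD
blocks would not exist and the Gabriel stage would have nothing to find.
The default 10 cM blocks at 400 kb/cM give blocks on the Mb scale, the
magnitude at which QTL intervals are reported in elite rapeseed.

Phenotypes follow an additive model in days:

$$y_{ijk} = \mu + e_j + \textstyle\sum_l \beta_l x_{il} + g_i + (ge)_{ij} + \varepsilon_{ijk}$$

with environment effects $e_j$, per-locus allele-substitution effects
$\beta_l$ on 0/1 DH dosages, an optional i.i.d. polygenic effect
$g_i \sim N(0, \sigma^2_G)$, genotype-by-environment deviations
$(ge)_{ij} \sim N(0, \sigma^2_{GE})$ and plot residuals
$\varepsilon \sim N(0, \sigma^2_e)$. Day counts are treated as continuous;
the discreteness of field scoring is small relative to the residual
standard deviation (about 2 days) and continuity keeps effect recovery
unbiased and testable in closed form. On an entry-mean basis over $E$
environments and $R$ replicates,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(ER)},$$

computed by `expectedH2` and estimated from data by `estimateH2` via the
balanced two-way ANOVA expected mean squares
($\hat\sigma^2_e = MS_E$, $\hat\sigma^2_{GE} = (MS_{GE}-MS_E)/R$,
$\hat\sigma^2_G = (MS_G - MS_{GE})/(ER)$). The mean squares are computed
directly from cell means, which is exact for balanced tables and avoids
building a genotype-by-environment interaction design matrix with
hundreds of levels; unbalanced tables are rejected rather than silently
mis-estimated. The study-scale defaults — 7 founders, subfamilies of
60/60/60/60/60/54 (354 lines), 5 environments, 2 replicates, and variance
components $\sigma^2_G = 1.953$, $\sigma^2_{GE} = 1$, $\sigma^2_e = 2$
giving $H^2 = 1.953/2.353 \approx 0.83$ — reproduce the design and
heritability of the elite winter-rapeseed trial the package models. The
simulated population size is exposed as a parameter because the source
material is itself ambiguous between 352 and 354 analyzed lines.

## Marker QC and SNaP calling

`qcFilter` excludes markers with more than 10% missing data or minor
allele frequency below 5%, and individuals with more than 10% missing
data. "Missing" counts both random missingness and systematic call
failure. Because removing markers changes individual missingness
denominators (and vice versa), the filter iterates to a fixed point, which
makes it idempotent — filtering a filtered matrix changes nothing.

The two missing states are deliberately distinct. Random missingness is
assay noise; *systematic* failure is signal: an array probe whose binding
site is deleted fails in every carrier. `callSnap` turns this into SNaP
(single nucleotide absence polymorphism) markers: candidates are loci
with at least 10% failed calls; within each subfamily where both states
occur, presence:absence counts are tested against 1:1 with a one-df
χ² without continuity correction, and candidates are accepted when no
polymorphic subfamily rejects 1:1 at α = 0.05. The uncorrected χ² is the
only variant that reproduces the published subfamily probabilities this
stage is validated against (29:31 gives p = 0.796; with the Yates
correction it would give 0.897). Because real populations show loci that
fit 1:1 in some subfamilies and not others (segregation distortion during
DH production is common in *B. napus*), a permissive `mode = "any"` is
available; the strict "all" default favours marker quality. Accepted
markers are recoded as dominant presence/absence calls (1 = absent probe
site) and can be scanned like any other marker.

## Association model

`associationScan` implements a polygenic score test per environment:
under the null, $y = X\alpha + u + \varepsilon$ with
$\mathrm{var}(u) \propto K$, the allele-sharing (IBS) kinship matrix, and
$X$ an intercept plus the leading kinship principal components (default
2). The variance ratio is estimated by REML profiled over a single
parameter on the kinship eigenbasis, then each marker is scored as

$$\chi = \frac{(g^\top P y)^2}{g^\top P g \cdot \hat\sigma^2}, \qquad
P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}.$$

This is the classic mixed-model score ("mmscore") statistic: with
identity kinship and no PCs it reduces exactly to the marker-regression
score χ², and under a structured polygenic null it keeps the genomic
inflation factor λ near 1 where the unadjusted scan inflates severely
(both properties are tested). Missing genotypes are mean-imputed for the
score — an imputed value carries no association signal — while the $n$
in the explained-variance formula $R^2 = \chi/(n-2+\chi)$ is the number
of non-missing phenotype–genotype pairs for that marker. Scans are run
per environment (matching how multi-environment field trials are
reported) and aggregated only at QTL declaration: a marker is significant
at Benjamini–Hochberg FDR ≤ 0.1 within its scan, suggestive at
−log₁₀(p) ≥ 3, and a QTL is an LD block containing a marker significant
in at least 2 of 5 environments. A qualifying marker that falls in a
recombination gap between blocks (typical for an SV presence/absence
call typed independently of the array) is reported as a point QTL rather
than dropped. One printed headline pair elsewhere reported for such an
added SV marker (LOD 4.57 with R² = 5.64%) is not exactly reconcilable
with the R² formula at n = 352 under a 1-df χ²-to-LOD conversion; the
package therefore treats the formula, not that pair, as normative.

## LD blocks

`dprime` reads two-locus haplotype counts directly from the homozygous
lines (no phasing needed; an EM fallback handles diploid 0/1/2 input for
generality), computes $D = p_{AB} - p_A p_B$ and $D' = D/D_{max}$, and
puts a two-sided 90% confidence interval on $|D'|$ by normalizing the
multinomial likelihood over a grid of $|D'|$ values (step 0.001) with
allele frequencies fixed at their sample estimates — the
Wall–Pritchard/Haploview construction. Pairs are *strong LD* when the CI
lower bound is ≥ 0.70 and the upper ≥ 0.98, *strong recombination* when
the upper bound is < 0.90, otherwise uninformative. `findBlocks` accepts
a span of consecutive markers as a block when ≥ 95% of its informative
pairs are strong LD, resolving overlaps longest-first. These are the
Haploview defaults, fixed here because the block method is cited in the
field without parameters. Blocks are reported in 1-based inclusive
coordinates with sizes in kb, and written as 0-based half-open BED at the
I/O boundary.

## SV catalog and genotyping

SV records live in `GRanges` (1-based, closed intervals — the
Bioconductor convention; BED/bedGraph conversion happens only at I/O, so
half-open boundary semantics are preserved by the converters and covered
by boundary tests). Deletions span their reference footprint; insertions
anchor at a single base. Founder-allele classification: monomorphic means
all founders with known alleles agree — including all-alternate, a shared
difference from the reference — polymorphic otherwise. Size classes use
half-open, lower-inclusive bins [30, 100), [100, 1000), [1000, 10000),
≥ 10 kb; the lower-inclusive choice is documented because published size
histograms rarely state their boundary convention. Gene intersection
distinguishes intragenic overlap from promoter overlap, the promoter
being a fixed 10 kb window upstream of the annotated gene start on the
coding strand — an approximation of "upstream of the start codon", since
toy GFF annotations carry no start-codon features. The flowering filter
is a case-insensitive substring match of the functional annotation
against a configurable keyword list (flower, vernalization, photoperiod,
circadian, floral, vegetative to reproductive, vegetative phase change,
pollen, carpel, sepal, petal).

`predictAmplicons` does interval bookkeeping, not thermodynamics: a
deletion strictly between the primer footprints shortens the product by
its size, an insertion lengthens it, and an SV overlapping a primer
footprint abolishes the product. Two published assay rows whose product
differences disagree with their stated SV sizes (797/519 vs a 288 bp
event, and 419/362 vs 64 bp) are attributable to unresolved reference
bases (Ns) in the target gene and are excluded from the conservation
checks.

`segregationTest` is the same uncorrected one-df χ² as in SNaP calling,
with significance stars at 0.05/0.01/0.001. `allelicEffects` collapses
replicates to entry means per environment and tests carrier vs reference
class means with a two-sided pooled-variance Student's t test, effects
reported in days (negative = carriers earlier).

### NMC deletion genotyping

`nmcGenotype` forms the normalized mean coverage of a target interval
against a baseline (by default the flanking sequence on the same track)
and calls: deletion below 0.5, reference above 1.5, ambiguous in the
closed interval between — boundary values are deliberately ambiguous.
Two normalizations are offered because they answer different questions.
The raw target/baseline ratio puts a homozygous deletion near the
residual mapping rate and a heterozygote near 0.5 — exactly on the call
boundary, where Poisson noise would flip calls arbitrarily. For panel
genotyping, `singleCopyBaseline = TRUE` halves the baseline to its
haploid equivalent (the relative-copy-number convention): a two-copy
reference individual then sits near 2, a heterozygote near 1, and a
homozygous deletion near 0.1, so the three classes separate cleanly and
heterozygotes are never miscalled as deletion or reference — they land in
the ambiguous class, which is why coverage-based calling alone cannot
type heterozygotes and is cross-checked against PCR calls via
`concordance`. At 30× coverage over a ~300 bp interval the homozygous
classes are called essentially without error; accuracy degrades with
shallower depth and shorter intervals roughly as the standard error of a
Poisson mean.

## Motif scanning

`readJaspar` parses JASPAR-format count matrices; scoring converts counts
to probabilities with a total pseudocount of 0.8 distributed by the
background frequencies (the JASPAR convention, configurable) and takes
base-2 log-odds against the background (uniform by default). `scanPFM`
scores every window on both strands, skips windows containing N, and
reports relative scores $(s - s_{min})/(s_{max} - s_{min})$, so any
motif's consensus scores exactly 1. The default reporting threshold of
0.8 relative score is conservative; no p-value calibration is attempted
(relative score only). The scanner is validated against an exhaustive
per-window oracle. The biological claim this stage supports — that a
deleted intronic sequence contains circadian-regulator (CCA1/LHY-class)
binding sites — is reproduced on synthetic fixtures: a consensus site
planted in a simulated deleted sequence is found by the corresponding
matrix; the true deleted sequence is not distributed with the package.

## The pipeline and reproducibility

`pipelineConfig` collects every threshold (QC 10%/5%/10%; SNaP 0.10 and
α = 0.05; FDR 0.1; suggestive 3.0; ≥ 2 environments; Gabriel
0.70/0.98/0.90/95%; promoter 10 kb; NMC 0.5/1.5; motif 0.8) with the
analysis defaults above, all overridable. `runPipeline` executes
simulate → QC → SNaP → scan → blocks → QTL → SV catalog → SV genotyping →
motif scan, writing per-stage TSVs, the YAML-serialized configuration and
a record-count manifest into a run directory; the seed is embedded in
output headers and identical configurations produce byte-identical
outputs. Stage toggles allow user-supplied intervals to replace the QTL
stage. The package's functions are the primary interface; a thin
option-parsing wrapper ships in `inst/scripts/run_pipeline.R`.

## Problem sizes used in the tests

The shipped tests run the full machinery at desk scale: populations of
60–354 lines, 2–4 chromosomes with 30–125 markers each, 20 seeds for
heritability recovery, 50 seeds for effect recovery, 3 seeds for scan
calibration, and 250-accession depth panels at 30×. These sizes were
chosen so the statistical targets (binomial/χ² standard errors, score-test
calibration) are resolvable with comfortable margins while the whole
suite completes in about a minute.

## What the generator does not emulate, and other limitations

- No read-level simulation: depth tracks are Poisson per base, with no
  mapping-quality structure, GC bias or junction reads; FASTQ-level
  effects (soft-clipping at deletion breakpoints, split reads) are out of
  scope, so passing NMC tests say nothing about aligner behaviour.
- No vernalization physiology or QTL-by-environment crossover structure:
  GxE is exchangeable Gaussian noise, while real flowering QTL can be
  environment-specific in sign.
- Founder LD is a two-haplotype block mosaic; real elite pools have
  deeper ancestral genealogies, so real block-boundary uncertainty is
  larger than in the planted-block tests.
- Segregation distortion is off by default and injected only through
  per-locus viability weights, enough to exercise the χ² stage but not a
  model of DH-production biology.
- The score test mean-imputes missing genotypes; with > 10% missingness
  (excluded by QC anyway) its calibration would degrade.
- Population-wide LD blocks are computed on the combined DH panel; the
  alternative (per-subfamily blocks) is not implemented, matching how the
  combined analysis is usually reported.
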