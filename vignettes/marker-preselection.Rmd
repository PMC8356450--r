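---
title: "Marker preselection and Mendelian-sampling diagnostics on simulated breeding populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker preselection and Mendelian-sampling diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Dense genotyping panels carry many markers that segregate independently of
every locus affecting the trait being predicted. `FstPresel` simulates a
breeding population in which the truth is known — 200 QTL confined to 2 of
30 chromosomes — so that every marker can be labelled truth-linked (`HQ`,
on a QTL-bearing chromosome) or truth-unlinked (`LQ`), and asks three
questions:

1. How much do unlinked markers degrade single-step GBLUP accuracy when
   they enter the genomic relationship matrix?
2. Can the population statistic F_ST, computed between extreme-phenotype
   tails of the training population, preselect trait-relevant markers as
   well as the absolute back-solved SNP effect, while being less exposed to
   the winner's curse of re-using training data?
3. How well do marker-based genomic relationships capture the
   Mendelian-sampling (MS) component of the QTL relationships — the part of
   relatedness that pedigree expectations cannot see?

# The simulation model

## Genome and linkage disequilibrium

The genome is 30 chromosomes of 100 cM with evenly spaced biallelic SNPs
and QTL positions drawn uniformly on the designated chromosomes, distinct
from marker positions. All loci start at allele frequency 0.5 with
independent alleles; linkage disequilibrium is created purely by drift
through 2070 generations of random mating (random union of gametes from two
distinct parents, no selfing) over a population-size schedule with a
bottleneck at generation 2000. Meiosis draws Poisson(length/100 cM)
crossovers per chromosome at uniform positions without interference, with
independent assortment across chromosomes.

The size schedule is the one free quantity of this protocol: only its range
(600–4000), the bottleneck generation and the final size (4000 = the
founders of the selected population) are fixed by the design. A schedule
that stays at the final size until the bottleneck builds too little LD at
the target marker density, which we verified both by simulation and with
the standard recursion for E[r²] under drift and recombination,
x ← (1−c)²(1−1/2N)x + 1/2N. The default schedule therefore holds the
population at 2200, crashes to 600 at generation 2000 and recovers linearly
to 4000 by generation 2070; the recursion locates this plateau as the one
whose realized mean r² between consecutive SNPs at full density (259
SNPs/cM) matches the design's stated LD regime (≈ 0.32). The acceptance
suite re-measures this from scratch. `historicalConfig(sizes = ...)`
accepts any explicit schedule.

## Marker panels under drift

Over two thousand generations of drift many loci fix. Simulators of the
QMSim family resolve this by drawing the requested marker and QTL panels
from loci still segregating in the last historical generation, and we do
the same: `genomeConfig(snpCandidateFactor = k)` lays out a k-fold denser
candidate grid, and after the historical phase the requested number of
markers per chromosome is sampled from the segregating candidates
(`qtlCandidateFactor` plays the same role for QTL; a shortfall of
segregating QTL candidates is an error, a shortfall of marker candidates
falls back to monomorphic fill-ins with a warning). With factor 1 the panel
is the simulated grid itself and loci that fixed stay in the map as
monomorphic markers: they are excluded from VanRaden denominators and score
F_ST 0, so indexing is never perturbed.

## Trait and selected population

QTL allele-substitution effects are |Gamma(shape 0.4)| magnitudes with
Bernoulli(0.5) signs — the unsigned Gamma alone would make breeding values
frequency-dominated — rescaled by one global constant so that the variance
of the true breeding value (TBV = cross-product of QTL dosages and effects)
among the founders equals the genetic variance 0.4. Phenotypes are TBV +
N(0, 0.6), giving heritability 0.4.

The founders (500 males, 3500 females at full scale) start seven discrete
generations of 3500 progeny. From generation 2 on, parents are ranked on
pedigree EBVs from an A-matrix BLUP fit (variance components fixed at the
simulation truth, λ = 1.5) of all phenotypes recorded so far; the bottom
50% of sires and 20% of dams are replaced by the top-ranked young
candidates of the previous generation. Dams are shuffled and allocated
evenly to sires, one progeny per dam per generation. Generations 1–6 are
phenotyped at birth and half of each, at random, is genotyped (the
training set); generation 7 is fully genotyped and unphenotyped (the
validation set). Founders are neither phenotyped nor genotyped.

# Prediction machinery

* **A** — numerator relationship matrix by the tabular method; A22 is its
  genotyped block.
* **G** — VanRaden: G = ZZ′ / 2Σp(1−p), Z the 0/1/2 codes centered by 2p,
  with p the observed frequency over all genotyped individuals (training
  plus validation, the BLUPF90 default); monomorphic loci drop out of both
  numerator and denominator.
* **H⁻¹** — A⁻¹ + (G*⁻¹ − A22⁻¹) on the genotyped block, with
  G* = 0.95 G + 0.05 A22. The 5% pedigree blend is applied only where an
  inverse is required (H⁻¹ and effect back-solving); all similarity
  metrics use the raw G.
* **Mixed model** — mean plus animal effect; dense Cholesky solves up to a
  configurable size (default 8000 equations), Jacobi-preconditioned
  conjugate gradient above it (relative-residual tolerance 1e-10).
* **SNP effects** — back-solved from the all-marker GEBVs of the genotyped
  training individuals as û = DZ′(ZDZ′)⁻¹â with D = I, (ZZ′)⁻¹ taken via
  the blended G scaled by the VanRaden denominator.
* **Accuracy** — Pearson correlation of EBV with TBV over the validation
  generation.

# Preselection

F_ST follows Nei: the genotyped-and-phenotyped training individuals are
ranked on phenotype; the bottom and top 5% (stable tie-break by id) form
two subpopulations, and per SNP F_ST = (H_T − H_S)/H_T with H_T = 2p_Tq_T
from the pooled frequency and H_S the size-weighted mean subpopulation
heterozygosity (0 where H_T = 0). Ranking by F_ST or |û| breaks ties by
(chromosome, position). Subset sizes mirror the full design's 1–50 k
panels as marker fractions (desk scale: 12, 116, 232, 347, 463, 579 of
9000). Exclusion panels remove the top- or bottom-ranked k unlinked
markers from the full panel.

# Mendelian-sampling diagnostics

All pairwise metrics run over the off-diagonal unique pairs of the
genotyped **training** individuals, and every standard deviation is taken
over that same pair set — the diagonal-inclusion convention is not fixed by
the design, and using one pair set everywhere keeps the three metrics
consistent:

* correlation of G_M with G_QTL, plain and centered by A22 (the centered
  variant isolates the MS component);
* directional MS: |g_m − a22|/sd(G_M), signed by whether the marker and
  QTL deviations from the pedigree expectation agree in direction; pairs
  whose QTL deviation is below 1e-8·sd(G_QTL) count as agreeing (they are
  directionless);
* MS error (%): 100·|(m − q)/q| with m, q the deviations standardized by
  their own matrix sd; pairs with numerically zero QTL deviation are
  excluded and counted. Values under 100 mean the marker relationship is
  strictly closer to the QTL relationship than the pedigree expectation.

Genetic variance explained weights each QTL by 2p(1−p)a² and counts it as
tagged when at least one subset marker reaches r² > 0.9 with it among the
genotyped training individuals.

# Scale presets and problem sizes

`presetConfig()` bundles three scales. The full design (`full`: 777 k
SNPs, 24.5 k individuals) is cluster-sized and not run here. The `desk`
preset keeps the full design's ratios — 30 chromosomes, 200 QTL on 2,
subset sizes scaled by the same marker fractions — at 9 k SNPs, 400
founders (50 sires + 350 dams) and 350 progeny per generation, with the
historical sizes divided by ten (constant 400, bottleneck 60) as the
scaled-down protocol prescribes; one desk replicate simulates roughly
150 k candidate loci through 2070 generations in about a minute and the
full marker-set grid in two to three. The acceptance suite runs five desk
replicates plus one full-density single-chromosome LD calibration; those
problem sizes were chosen so the whole study re-runs on a laptop core
within minutes while leaving the full-scale code path identical. The
`micro` preset is for unit tests.

Desk-scale caveats, visible in the diagnostics rather than hidden: with a
tenth of the effective population size, founders carry appreciable
background relatedness that the pedigree (which assumes unrelated founders)
cannot express. Genome-wide realized kinship then deviates from A22
coherently across chromosomes, so the centered correlation between
unlinked-marker and QTL relationships does not collapse as close to zero
as it does at full scale, and baseline accuracies sit somewhat below their
full-scale counterparts. Granularity matters at the small end of the
subset grid, too: the desk analogue of a 1 k panel is 12 markers ranked
from extreme tails of 52 individuals each, so the smallest-subset
sensitivity and accuracy are intrinsically noisier than their full-scale
counterparts. The qualitative contrasts — accuracy ordering of marker
classes, the persistence of F_ST-preselected accuracy relative to
effect-preselected accuracy, which exclusions help — are the quantities
the desk scale is designed to preserve, and the acceptance suite asserts
the full-scale-sharp properties as stated, letting the scale-sensitive
ones fail visibly rather than relaxing them.

# Numerical and degenerate-input choices

* Variance components are never estimated; the simulation truth is used
  (the full design ran its solver with given parameters).
* `buildG` errors on an all-monomorphic subset; genotype codes outside
  {0,1,2} are rejected.
* A singular unblended ZZ′ or G* raises an error that points to blending
  (observed-frequency centering always makes raw ZZ′ singular, since
  centered columns sum to zero).
* Accuracy and matrix correlations on zero-variance inputs return NA with
  a warning rather than failing a whole replicate.
* All randomness flows through R's RNG, including inside the compiled
  meiosis kernel; a master seed derives one child seed per replicate, so
  seeded runs are bit-reproducible and replicates are independent.

# What the generator does not emulate

No mutation, no non-additive gene action, no sex chromosomes, no
overlapping-generation age structure, no genotyping error or imputation,
no minor-allele-frequency ascertainment beyond the segregating-candidate
panel draw. Passing the desk-scale checks shows the machinery reproduces
the designed contrasts under drift-built LD; it does not certify behavior
on real livestock data, where LD structure, family sizes and selection
histories are far less regular.
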