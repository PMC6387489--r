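---
title: "Marker prioritization by phenotype-tail FST and its effect on GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker prioritization by phenotype-tail FST and its effect on GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fstgblup)
```

## The problem

Genomic selection predicts breeding values from genome-wide marker panels.
As panels grow dense, prediction accuracy saturates: the genomic
relationship matrix **G** stops improving once markers saturate the
genome's effective number of independent segments, and markers unlinked to
causal loci only add frequency-weighted noise to realized relationships.
One response is to *prioritize* markers before building **G**.  This
package implements a population-genetic prioritization: score each SNP by
Wright's fixation index between the low and high phenotype tails of the
training cohort, keep the top-scoring subset, and quantify what that does
to genomic similarity, variance components, and GBLUP accuracy — all on
simulated populations where the true breeding values are known.

## The model chain

### Simulated population

`sim_population()` emulates a livestock genetic-evaluation design in two
stages.

1. **Historical phase** (`sim_founders()`).  Biallelic SNPs are uniformly
   spaced on `n_chromosomes` chromosomes of equal genetic length; QTL
   positions are uniform and disjoint from SNPs.  Founder allele
   frequencies are drawn from U(0.05, 0.95) at linkage equilibrium, then
   random mating through a configurable bottleneck builds linkage
   disequilibrium by drift.  Adjacent-marker LD (mean dosage-correlation
   r²) is a monotone function of bottleneck intensity; `calibrate_ld()`
   maps (bottleneck size, burn-in length) to realized r².  The shipped
   presets, calibrated at a 0.2 cM marker spacing, are
   `moderate_ld` (N = 50 for 45 generations, r² near 0.3) and `high_ld`
   (N = 20 for 80 generations, r² near 0.7), each followed by a
   2-generation expansion to the founder-cohort size.  Loci fixed by drift
   are dropped, so the realized panel is somewhat smaller than `n_snps`.
2. **Selected phase** (`sim_generations()`).  A founder cohort (default
   100 males, 2,000 females) is bred for 7 discrete generations: every
   breeding female has one progeny by a randomly assigned breeding male,
   progeny sex is Bernoulli(1/2), and each generation 50% of breeding
   males and 20% of females are replaced by the top-ranking progeny
   (truncation selection, poorest current breeders culled).  The default
   ranking criterion is the individual's own phenotype; a recursive
   parent-average index and random selection (a drift control) are
   alternatives.  Generation 6 is returned as the training cohort and
   generation 7 as validation.

Meiosis uses the Haldane model: crossover counts are Poisson with mean
equal to the chromosome length in Morgans, positions uniform, no
interference.  This is the simplest standard choice and all downstream
statistics depend on recombination only through realized LD.

### Trait

A single additive trait: 200 QTL effects with Gamma(shape 0.4) magnitudes
and random signs, rescaled once (`standardize_trait()`) so the
true-breeding-value variance in the base generation is exactly
h² · var_p = 0.3 and the residual variance var_p (1 − h²) = 0.7, with
phenotypes y = mean + TBV + e.  The Gamma shape makes a few QTL carry most
of the variance, the architecture under which tail-differentiation scoring
is informative.

### FST scoring

The training cohort is split at the 5% and 95% empirical phenotype
quantiles (`partition_by_phenotype()`; ties broken by index, so a cohort of
15,000 yields exactly 750 + 750 tail animals).  For each locus, with tail
frequencies p_S1, p_S2 and sizes n_S1, n_S2:

- H_T = 2 p̄ q̄, with p̄ the individual-weighted pooled-tail frequency,
- H_S = (n_S1 H_S1 + n_S2 H_S2) / (n_S1 + n_S2), H_Si = 2 p_Si q_Si,
- FST = (H_T − H_S) / H_T.

With this pooling H_S ≤ H_T algebraically, so scores lie in [0, 1]; loci
monomorphic across both tails carry no information and are scored 0 and
flagged.  The middle group S0 plays no role in scoring.  `select_top_k()`
ranks by score with genome-order tie-breaks; `select_random_k()` is the
seeded random control.

### Relationship matrices

- `grm_vanraden()`: method-1 realized relationships, dosages centered by
  twice the observed frequency over all analyzed individuals (training and
  validation together — prioritization changes *which* loci enter G, never
  how G is normalized), denominator 2Σp(1−p), plus a 1e-8 diagonal ridge
  so downstream REML stays well-posed.
- `pedigree_a_matrix()`: the tabular (recursive) expected additive
  relationship matrix, with cycle detection and internal topological
  sorting.
- `genomic_similarity()`: identity-by-state allele sharing,
  sim(i, j) = 1 − mean|d_i − d_j| / 2 ∈ [0, 1].
- `od_histogram()` bins off-diagonal coefficients at
  ±0.05, ±0.03, ±0.01 (half-open bins, closed on the left) to contrast the
  realized and expected relationship distributions.

### GBLUP by AI-REML

`gblup()` fits y = Xb + u + e, u ~ N(0, K σ²_u), by restricted maximum
likelihood.  The kernel is eigendecomposed once; score, average-information
matrix and log-likelihood are evaluated in the rotated basis where the
covariance is diagonal, so each iteration is O(n p).  When an AI step
proposes a component below the 1e-10 floor the update falls back on the
EM-REML step (which cannot leave the parameter space), and an AI step that
lowers the likelihood is halved.  Convergence is declared at a relative
parameter change below 1e-8 or a log-likelihood change below 1e-6; these
tolerances are the package's own choice.  Genotyped-but-unphenotyped
individuals (the validation cohort) are part of K and receive predictions
σ²_u K[·, train] P y, the BLUP of their breeding values; this matches how
joint training + validation evaluation is normally run.  Accuracy is the
Pearson correlation between validation GEBVs and true breeding values
(simulation) or phenotypes adjusted for fixed effects (`kfold_cv()`, the
real-data protocol).  In simulated mode the only fixed effect is the
intercept, since the simulated phenotype has only an overall mean;
`gblup()`'s X argument accepts arbitrary covariates for real data.

### The experiment grid

`run_experiment()` replicates the whole chain: per replicate it simulates
a population, samples 2/3 of the training generation (phenotyped) and 1/3
of the validation generation, scores FST on the training sample, and for
every cell of {method} × {density ladder} selects markers, builds G over
training + validation, fits GBLUP and evaluates validation accuracy; a
full-panel cell is always included and random subsets are redrawn each
replicate.  The ladder is expressed as fractions of the realized panel
(the reference design's 2.5K–160K of 400K corresponds to 0.625%–40%), so
the same relative grid applies at any scale.  One master seed drives
everything through `derive_seeds()`, a draw of per-stage seeds from the
seeded RNG; repeated runs are identical.  `report_tables()` writes the
similarity, variance-component and accuracy tables and an
accuracy-versus-density plot.

## Quality control and file formats

`qc_filter()` implements the standard array-QC chain for user data:
individuals below 90% call rate are dropped first, then SNPs by call rate,
minor allele frequency (> 0.05), and heterozygote deviation, formalized as
|observed het − 2p̂q̂| < 0.15 since "deviation from Hardy–Weinberg" is
conventionally reported without a formula.  `read_plink()`/`write_plink()`
speak the PLINK text dialect with the counted allele defined as the
alphabetically first allele observed at each locus, which makes round
trips lossless; `write_cohort()` exports a simulated cohort as
.ped/.map + phenotype and pedigree tables.

## Design choices where the design was open

- **Historical phase instead of mutation–drift equilibrium.**  A desk-scale
  simulator cannot reproduce a 1,000-generation coalescent-like history;
  drift through a short bottleneck is the cheapest mechanism that gives a
  *tunable* adjacent-marker r², which is the statistic the study design
  actually conditions on.  The price is a drifted (U-shaped) allele
  frequency spectrum and some loss of loci to fixation.
- **Selection criterion.**  Genetic-evaluation EBVs inside the simulator
  would require a per-generation mixed-model solve; own-phenotype
  truncation gives the needed selected, structured population at h² = 0.3
  with a monotone response, and is the default.
- **QTL effect signs** are ±1 with equal probability; the Gamma
  distribution supplies magnitudes only.
- **Panel density of the shipped desk preset** (5,000 SNPs on 10 × 100 cM)
  is chosen so the panel is *saturating* — dense relative to the effective
  number of segments implied by the bottleneck — because the reference
  design's 400K panel is deep in that regime.  Sparser desk panels
  under-recover heritability for reasons that are pure density artifacts.
- **Problem sizes.**  The package's own studies run at desk scale:
  10,000 SNPs / 200 QTL / 2,100 founders / 2,000 animals per generation
  for trait-construction checks (5 replicate seeds; at that 0.1 cM
  spacing the moderate-LD burn-in realizes a somewhat higher adjacent r²
  than its 0.2 cM calibration point, which the trait checks do not depend
  on), and 2,400 SNPs / 1,260 animals for the ordering studies in the
  test suite.  These sizes keep a full replicate in the tens of seconds
  on one CPU while leaving every qualitative contrast intact.

## What the simulator does and does not emulate

It reproduces: tunable adjacent-marker LD, a selected multi-generation
population with sex-specific replacement, a standardized h² = 0.3 trait
with leptokurtic QTL effects, and the training/validation generation
structure.  It does not model mutation, crossover interference,
overlapping generations beyond the replacement scheme, genotyping error or
missingness (QC exists for user data, the simulator emits complete
genotypes), or sequence-level realism.  Passing tests therefore show that
the *method chain* behaves as the study design predicts under a clean,
structured population — not that any particular real panel will show the
same magnitudes.  One known qualitative divergence: with a drifted founder
spectrum the IBS similarity of small FST-prioritized panels can sit below
the random-panel similarity (top-scoring loci tag segregating QTL and so
avoid frequency extremes), whereas the reference design — whose panel is
ascertained at intermediate frequencies in a mutation–drift-equilibrium
population — reports the opposite ordering.  The similarity *flatness*
under random selection and all accuracy orderings are scale-robust.

## Numerical notes and degenerate inputs

Variance components are floored at 1e-10 during iteration; boundary
estimates are flagged.  K eigenvalues are clipped at zero.  Monomorphic
loci are dropped from G (message) and scored 0 by FST (flagged).  Constant
phenotype vectors, empty tails, exhausted middle groups, cyclic pedigrees,
self-parentage, over-filtered QC output, non-biallelic or ragged PLINK
records are all rejected with specific errors.  Ties — in phenotype order
statistics and FST ranks — are broken by index/genome order so every
result is reproducible.

## Limitations

FST tail scoring uses the training phenotypes that the GBLUP later fits;
the package mirrors that protocol deliberately, but users applying it to
real data should note the selection step is not independent of the
training response, and validation must come from individuals outside the
scoring cohort (the package's validation generation never enters scoring).
Single trait, additive effects only; no dominance or epistatic kinships;
no single-step (pedigree + genomic) evaluation; no imputation — filtered
real data must be complete or missingness-tolerated at the
allele-frequency stage only.
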