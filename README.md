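# fstgblup

Marker prioritization for genomic selection: score SNPs by Wright's
fixation index (F<sub>ST</sub>) between the low and high phenotype tails of a
training population, build genomic relationship matrices from the
prioritized subset, and measure what that does to variance components and
GBLUP prediction accuracy.

## Who this is for

Animal/plant breeding researchers studying why prediction accuracy
saturates on high-density panels, and anyone who wants a compact, fully
seeded in-silico testbed for marker-subset strategies: a forward-in-time
simulator of selected livestock populations with tunable linkage
disequilibrium, the tail-F<sub>ST</sub> scoring chain, relationship-matrix
construction, and a self-contained AI-REML GBLUP.

## The method

Training individuals are split at the 5% and 95% empirical phenotype
quantiles into tails S1 and S2.  For each SNP, with tail allele
frequencies p<sub>Si</sub> and sizes n<sub>Si</sub>:

    H_Si = 2 p_Si q_Si
    H_S  = (n_S1 H_S1 + n_S2 H_S2) / (n_S1 + n_S2)
    H_T  = 2 p̄ q̄          (p̄ = pooled-tail frequency)
    F_ST = (H_T − H_S) / H_T ∈ [0, 1]

SNPs in strong association with the trait differentiate the tails and
score high.  The top-k subset (vs a random subset of equal size) enters a
VanRaden method-1 genomic relationship matrix
G = ZZ′ / 2Σp(1−p), and the mixed model

    y = Xb + u + e,   u ~ N(0, G σ²_u),   e ~ N(0, I σ²_e)

is fitted by average-information REML (EM fallback, eigendecomposition
internals).  Accuracy is cor(GEBV, TBV) in a validation generation that
never touches the scoring step.  `run_experiment()` sweeps a ladder of
panel densities × {fst, random} over replicated simulations.

## Worked example

```r
library(fstgblup)
sim <- sim_population(
  spec = genome_spec(n_chromosomes = 10, chromosome_length_cM = 100,
                     n_snps = 2400, n_qtl = 150),
  schedule = population_schedule(
    historical = data.frame(generations = c(45, 2), size = c(50, 1260)),
    founder_males = 60, founder_females = 1200, n_generations = 7),
  trait = trait_architecture(h2 = 0.3, var_p = 1), seed = 42)
sim
#> Simulated population: 1592 SNPs, 109 QTL, h2 = 0.3
#>   base 1260 | training (G6) 1200 | validation (G7) 1200 individuals
#>   mean TBV by generation: 1.977 2.020 2.272 2.502 2.661 2.787 2.911 3.097

tails <- partition_by_phenotype(sim$train$phenotype)
tails
#> Phenotype tails: S1 60 | S0 1080 | S2 60 (quantiles 0.05/0.95)

scores <- fst_scores(sim$train$geno, tails)
top    <- select_top_k(scores, 120)
geno   <- rbind(sim$train$geno, sim$valid$geno)
fit    <- gblup(setNames(sim$train$phenotype, sim$train$ids),
                grm_vanraden(geno, top))
summary(fit)
#>  component estimate      se
#>   sigma2_u   0.1303 0.03126
#>   sigma2_e   0.7554 0.03212
#> Heritability: 0.147 (se 0.031)
#> logLik -482.745 after 17 iterations (converged)

accuracy(predict(fit, as.character(sim$valid$ids)), sim$valid$tbv)
#> 0.552       # same pipeline with 120 random SNPs: 0.469
```

Interpretation: the simulated genome fixed about a third of its loci in
the LD-building bottleneck (2,400 nominal → 1,592 segregating SNPs); six
generations of truncation selection lifted mean TBV by ~1.1 genetic SD; a
120-SNP panel (7.5% of the markers) chosen by tail-F<sub>ST</sub> predicts
validation breeding values at r = 0.55, while 120 random SNPs reach 0.47.
The 120-SNP G captures only part of the genetic variance, hence the low
fitted h² relative to the simulated 0.30 — exactly the density effect the
package is built to study.  `run_experiment()` replicates this contrast
over a density ladder and seeds.

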