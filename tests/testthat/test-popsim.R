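test_that("founder pool is reproducible and segregating", {
  sp <- small_spec(n_snps = 100, n_qtl = 10)
  sch <- small_schedule()
  fp1 <- sim_founders(sp, sch, seed = 3)
  fp2 <- sim_founders(sp, sch, seed = 3)
  expect_identical(fp1$H1, fp2$H1)
  expect_identical(fp1$H2, fp2$H2)
  freq <- colMeans(fp1$H1 + fp1$H2) / 2
  expect_true(all(freq > 0 & freq < 1))
  fp3 <- sim_founders(sp, sch, seed = 4)
  expect_false(identical(fp1$H1, fp3$H1))
})

test_that("degenerate historical schedules are rejected", {
  sp <- small_spec(n_snps = 50, n_qtl = 5)
  sch <- small_schedule()
  sch$historical <- data.frame(generations = 5L, size = 1L)
  expect_error(sim_founders(sp, sch, 1), "at least 2")
})

test_that("zero burn-in founders sit at linkage equilibrium", {
  ## Monte-Carlo oracle: mean adjacent r2 between independent loci with N
  ## individuals, estimated over many independent pairs
  N <- 200
  set.seed(42)
  mc <- replicate(30, {
    g <- matrix(rbinom(N * 40, 2, runif(40, 0.05, 0.95)), N, 40, byrow = TRUE)
    mean(cor(g)[cbind(1:39, 2:40)]^2)
  })
  oracle <- mean(mc)                    # about 1/(N-1)
  sp <- genome_spec(n_chromosomes = 2, chromosome_length_cM = 100,
                    n_snps = 1000, n_qtl = 2)
  sch <- population_schedule(
    historical = data.frame(generations = 0L, size = N),
    founder_males = 2, founder_females = 2, n_generations = 1,
    training_generation = 1, validation_generation = 1)
  fp <- sim_founders(sp, sch, seed = 9)
  ld <- measure_adjacent_ld(fp$H1 + fp$H2, fp$map)
  expect_lt(abs(ld$mean_r2 - oracle), 0.5 * oracle)
  expect_lt(ld$mean_r2, 0.02)           # far below any bottleneck regime
})

test_that("stronger burn-in gives more adjacent LD, seed by seed", {
  sp <- genome_spec(n_chromosomes = 1, chromosome_length_cM = 100,
                    n_snps = 300, n_qtl = 2)
  mk <- function(gens, size) population_schedule(
    historical = data.frame(generations = c(gens, 1L), size = c(size, 150L)),
    founder_males = 2, founder_females = 2, n_generations = 1,
    training_generation = 1, validation_generation = 1)
  for (seed in 1:5) {
    strong <- sim_founders(sp, mk(25L, 30L), seed)
    weak <- sim_founders(sp, mk(2L, 150L), seed)
    r2_strong <- measure_adjacent_ld(strong$H1 + strong$H2, strong$map)$mean_r2
    r2_weak <- measure_adjacent_ld(weak$H1 + weak$H2, weak$map)$mean_r2
    expect_gt(r2_strong, r2_weak)
  }
})

test_that("adjacent-LD measurement matches the haplotype r2 formula", {
  ## four haplotypes at two loci: AB, AB, ab, aB
  ## pA = 0.5, pB = 0.75, D = 0.5 - 0.375 = 0.125,
  ## r2 = D^2 / (pA qA pB qB) = 1/3
  haps <- matrix(c(1, 1, 0, 0, 1, 1, 0, 1), 4, 2)
  pairs <- expand.grid(h1 = 1:4, h2 = 1:4)   # all ordered diploids
  geno <- haps[pairs$h1, ] + haps[pairs$h2, ]
  map <- data.frame(chr = 1, pos_cM = c(1, 2))
  ld <- measure_adjacent_ld(geno, map)
  expect_equal(ld$mean_r2, 1 / 3, tolerance = 1e-12)

  ## duplicated locus is in perfect LD with itself
  g2 <- cbind(geno[, 1], geno[, 1])
  expect_equal(measure_adjacent_ld(g2, map)$mean_r2, 1, tolerance = 1e-12)

  ## a monomorphic member is skipped, not scored
  g3 <- cbind(geno[, 1], 2)
  ld3 <- measure_adjacent_ld(g3, map)
  expect_equal(ld3$n_skipped, 1L)
  expect_true(is.nan(ld3$mean_r2))
})

test_that("trait standardization hits the target variances exactly", {
  set.seed(1)
  g <- matrix(rbinom(500 * 20, 2, 0.4), 500, 20)
  raw <- rgamma(20, 0.4) * sample(c(-1, 1), 20, TRUE)
  st <- standardize_trait(raw, g, h2 = 0.3, var_p = 1)
  expect_equal(var(drop(g %*% st$effects)), 0.3, tolerance = 1e-12)
  expect_equal(st$sigma2_e, 0.7)
  ## scale invariance of the raw effects
  st2 <- standardize_trait(2 * raw, g, h2 = 0.3, var_p = 1)
  expect_equal(st$effects, st2$effects, tolerance = 1e-12)
  ## h2 = 1 boundary
  expect_equal(standardize_trait(raw, g, 1, 1)$sigma2_e, 0)
  ## monomorphic base cannot be standardized
  expect_error(standardize_trait(raw, matrix(2, 5, 20), 0.3, 1),
               "cannot standardize")
})

test_that("phenotype selection produces a positive genetic trend", {
  resp <- vapply(1:5, function(seed) {
    sim <- sim_population(small_spec(n_snps = 150, n_qtl = 20),
                          small_schedule(n_generations = 5),
                          trait_architecture(), seed = seed)
    unname(rev(sim$gen_mean_tbv)[1] - sim$gen_mean_tbv[1])
  }, numeric(1))
  expect_true(all(resp > 0))
  ## order of magnitude: cumulative response should be a handful of
  ## i * h2 * sigma_p per-generation steps, far above drift
  expect_gt(mean(resp), 0.3)
  expect_lt(mean(resp), 3)
})

test_that("random selection shows no systematic trend (drift control)", {
  sch <- small_schedule(n_generations = 5)
  sch$selection <- "random"
  drift <- vapply(1:5, function(seed) {
    sim <- sim_population(small_spec(n_snps = 150, n_qtl = 20), sch,
                          trait_architecture(), seed = seed)
    unname(rev(sim$gen_mean_tbv)[1] - sim$gen_mean_tbv[1])
  }, numeric(1))
  expect_lt(abs(mean(drift)), 0.3)
})

test_that("pedigree structure is sound and deterministic end to end", {
  sim <- small_cohort()
  ped <- sim$pedigree
  off <- ped[ped$generation > 0, ]
  expect_true(all(off$sire %in% ped$id) && all(off$dam %in% ped$id))
  ## parents precede offspring and have the right sex
  sx <- setNames(ped$sex, ped$id)
  expect_true(all(sx[as.character(off$sire)] == 1L))
  expect_true(all(sx[as.character(off$dam)] == 2L))
  expect_true(all(match(off$sire, ped$id) < match(off$id, ped$id)))
  ## founders have unknown parents
  expect_true(all(ped$sire[ped$generation == 0] == 0L))
  ## phenotype = mean + tbv + residual with the standardized residual var
  res <- sim$train$phenotype - sim$train$tbv
  expect_equal(var(res), sim$trait$sigma2_e, tolerance = 0.2)
  ## full determinism of the pipeline under one seed
  sim2 <- sim_population(small_spec(), small_schedule(),
                         trait_architecture(), seed = 7)
  expect_identical(sim$train$geno, sim2$train$geno)
  expect_identical(sim$valid$phenotype, sim2$valid$phenotype)
})

test_that("base generation matches the target trait architecture", {
  sim <- small_cohort()
  expect_equal(var(sim$base$tbv), 0.3, tolerance = 1e-10)
  expect_equal(var(sim$base$phenotype), 1, tolerance = 0.2)
  ## regression of phenotype on TBV: slope 1, R2 near h2
  fit <- lm(sim$base$phenotype ~ sim$base$tbv)
  expect_lt(abs(unname(coef(fit)[2]) - 1), 0.25)
  expect_lt(abs(summary(fit)$r.squared - 0.3), 0.1)
})

test_that("replacement-rate shortfalls are reported", {
  sch <- small_schedule(males = 60, females = 20)
  expect_error(
    sim_population(small_spec(n_snps = 60, n_qtl = 6), sch,
                   trait_architecture(), seed = 2),
    "not enough selection candidates")
})
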