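## Shared fixtures, built in code.  The small cohort is simulated once per
## test run and reused by several files.

small_spec <- function(n_snps = 400, n_qtl = 40)
  genome_spec(n_chromosomes = 2, chromosome_length_cM = 100,
              n_snps = n_snps, n_qtl = n_qtl)

small_schedule <- function(n_generations = 7, males = 20, females = 250)
  population_schedule(
    historical = data.frame(generations = c(25L, 2L), size = c(50L, 300L)),
    founder_males = males, founder_females = females,
    n_generations = n_generations)

.small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.small_cohort_cache[[key]]))
    .small_cohort_cache[[key]] <- sim_population(
      small_spec(), small_schedule(), trait_architecture(), seed = seed)
  .small_cohort_cache[[key]]
}

## structured kernel for REML tests: genotypes of a bottlenecked pool
structured_kernel <- function(n = 300, n_snps = 600, seed = 5) {
  sp <- genome_spec(n_chromosomes = 2, chromosome_length_cM = 100,
                    n_snps = n_snps, n_qtl = 2)
  sch <- population_schedule(
    historical = data.frame(generations = c(20L, 1L), size = c(40L, n)),
    founder_males = 2, founder_females = 2, n_generations = 1,
    training_generation = 1, validation_generation = 1)
  fp <- sim_founders(sp, sch, seed)
  g <- (fp$H1 + fp$H2)[seq_len(n), , drop = FALSE]
  rownames(g) <- paste0("id", seq_len(n))
  suppressMessages(grm_vanraden(g))
}

## dense REML log-likelihood, the brute-force oracle (independent of the
## package's rotated-basis implementation)
dense_reml_ll <- function(su, se, y, X, K) {
  V <- su * K + se * diag(length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y)))
}
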