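## ---------------------------------------------------------------------------
## Forward-in-time simulator of a selected livestock population.
##
## The design emulates the classic two-stage scheme of livestock simulators:
## a historical random-mating phase (with an optional bottleneck) builds up
## linkage disequilibrium among uniformly spaced SNPs, then a founder cohort
## is drawn and bred through discrete generations of truncation selection
## with sex-specific replacement rates.  Phenotypes are the sum of an overall
## mean, additive QTL effects and a normal residual; heritability and
## phenotypic variance are fixed by rescaling the QTL effects in the base
## generation.
## ---------------------------------------------------------------------------

#' Genome specification
#'
#' Describes a genome of \code{n_chromosomes} chromosomes of equal genetic
#' length carrying uniformly spaced biallelic SNP markers and a set of
#' non-genotyped biallelic QTL placed uniformly at random, disjoint from the
#' SNP positions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_cM genetic length of each chromosome in
#'   centiMorgans.
#' @param n_snps total number of SNP markers (spread evenly over
#'   chromosomes, uniformly spaced within each).
#' @param n_qtl total number of QTL (uniform random positions, never
#'   coinciding with a SNP).
#' @return an object of class \code{genome_spec}.
#' @export
#' @examples
#' genome_spec(n_chromosomes = 2, n_snps = 100, n_qtl = 10)
genome_spec <- function(n_chromosomes = 10, chromosome_length_cM = 100,
                        n_snps = 2000, n_qtl = 150) {
  .check_count(n_chromosomes, "n_chromosomes")
  .check_count(n_snps, "n_snps", min = 2L)
  .check_count(n_qtl, "n_qtl")
  if (!is.numeric(chromosome_length_cM) || chromosome_length_cM <= 0)
    .fail("'chromosome_length_cM' must be positive")
  if (n_snps < 2 * n_chromosomes)
    .fail("need at least 2 SNPs per chromosome")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_cM = chromosome_length_cM,
                 n_snps = as.integer(n_snps),
                 n_qtl = as.integer(n_qtl)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("Genome: %d chromosomes x %g cM, %d SNPs, %d QTL\n",
              x$n_chromosomes, x$chromosome_length_cM, x$n_snps, x$n_qtl))
  invisible(x)
}

#' Population schedule
#'
#' Describes the demographic and selection design: a historical random-mating
#' phase given as a table of (generations, population size) rows, the founder
#' cohort drawn from the final historical generation, and the selected phase
#' with sex-specific replacement rates.  Defaults follow the reference design:
#' 50\% male and 20\% female replacement, seven selected generations with the
#' sixth used for training and the seventh for validation, one progeny per
#' mating and a 50\% progeny sex ratio.
#'
#' @param historical data frame with columns \code{generations} and
#'   \code{size}; each row is a phase of random mating at that size.  Zero
#'   total generations means founders are drawn at linkage equilibrium.
#' @param founder_males,founder_females numbers of male and female founders
#'   drawn from the historical pool.
#' @param n_generations number of selected generations bred after the
#'   founders.
#' @param male_replacement,female_replacement fraction of breeding males and
#'   females replaced by selected offspring each generation.
#' @param selection selection criterion for replacements: own phenotype
#'   (\code{"phenotype"}), a recursive parent-average index
#'   (\code{"pedigree_index"}), or \code{"random"} (drift control).
#' @param training_generation,validation_generation which selected
#'   generations to return as training and validation cohorts.
#' @return an object of class \code{pop_schedule}.
#' @export
population_schedule <- function(historical = data.frame(generations = c(40L, 2L),
                                                        size = c(60L, 600L)),
                                founder_males = 25, founder_females = 300,
                                n_generations = 7,
                                male_replacement = 0.5,
                                female_replacement = 0.2,
                                selection = c("phenotype", "pedigree_index",
                                              "random"),
                                training_generation = max(1L, n_generations - 1L),
                                validation_generation = n_generations) {
  selection <- match.arg(selection)
  if (!is.data.frame(historical) ||
      !all(c("generations", "size") %in% names(historical)))
    .fail("'historical' must be a data.frame with columns 'generations' and 'size'")
  if (any(historical$generations < 0) || any(historical$size < 2))
    .fail("historical phases need size >= 2 and non-negative generation counts")
  .check_count(founder_males, "founder_males")
  .check_count(founder_females, "founder_females")
  .check_count(n_generations, "n_generations")
  .check_frac(male_replacement, "male_replacement")
  .check_frac(female_replacement, "female_replacement")
  .check_count(training_generation, "training_generation")
  .check_count(validation_generation, "validation_generation")
  if (training_generation > n_generations ||
      validation_generation > n_generations)
    .fail("training/validation generations must not exceed n_generations")
  structure(list(historical = historical,
                 founder_males = as.integer(founder_males),
                 founder_females = as.integer(founder_females),
                 n_generations = as.integer(n_generations),
                 male_replacement = male_replacement,
                 female_replacement = female_replacement,
                 selection = selection,
                 training_generation = as.integer(training_generation),
                 validation_generation = as.integer(validation_generation)),
            class = "pop_schedule")
}

#' @export
print.pop_schedule <- function(x, ...) {
  cat(sprintf(paste0("Population schedule: %d historical generations ",
                     "(final size %d), %d/%d founder males/females,\n",
                     "  %d selected generations, replacement %g/%g (m/f), ",
                     "selection on %s\n"),
              sum(x$historical$generations),
              utils::tail(x$historical$size, 1),
              x$founder_males, x$founder_females, x$n_generations,
              x$male_replacement, x$female_replacement, x$selection))
  invisible(x)
}

#' Trait architecture
#'
#' A single additive trait controlled by the genome's QTL.  Effect magnitudes
#' are drawn from a Gamma distribution (shape 0.4 by default, so a few QTL
#' carry most of the variance) with random signs, and are rescaled in the
#' base generation so that the true-breeding-value variance equals
#' \code{h2 * var_p} and the residual variance \code{var_p * (1 - h2)}.
#'
#' @param h2 target narrow-sense heritability (default 0.3).
#' @param var_p target phenotypic variance (default 1).
#' @param mean overall phenotypic mean.
#' @param gamma_shape shape of the Gamma distribution of QTL effect
#'   magnitudes.
#' @return an object of class \code{trait_arch}.
#' @export
trait_architecture <- function(h2 = 0.3, var_p = 1, mean = 0,
                               gamma_shape = 0.4) {
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) .fail("'h2' must lie in [0, 1]")
  if (!is.numeric(var_p) || var_p <= 0) .fail("'var_p' must be positive")
  if (!is.numeric(gamma_shape) || gamma_shape <= 0)
    .fail("'gamma_shape' must be positive")
  structure(list(h2 = h2, var_p = var_p, mean = mean,
                 gamma_shape = gamma_shape),
            class = "trait_arch")
}

## ---- internal genome machinery --------------------------------------------

## Build the marker map: uniformly spaced SNPs, uniform random QTL, disjoint.
## Caller must have seeded the RNG.
.build_map <- function(spec) {
  nchr <- spec$n_chromosomes
  len <- spec$chromosome_length_cM
  snp_per <- rep(spec$n_snps %/% nchr, nchr)
  extra <- spec$n_snps %% nchr
  if (extra > 0) snp_per[seq_len(extra)] <- snp_per[seq_len(extra)] + 1L
  qtl_per <- rep(spec$n_qtl %/% nchr, nchr)
  extra <- spec$n_qtl %% nchr
  if (extra > 0) qtl_per[seq_len(extra)] <- qtl_per[seq_len(extra)] + 1L
  pieces <- vector("list", nchr)
  for (c in seq_len(nchr)) {
    spos <- len * (seq_len(snp_per[c]) - 0.5) / snp_per[c]
    qpos <- stats::runif(qtl_per[c], 0, len)
    while (any(qpos %in% spos))  # ties have probability zero, but be exact
      qpos[qpos %in% spos] <- stats::runif(sum(qpos %in% spos), 0, len)
    pieces[[c]] <- data.frame(
      chr = c,
      pos_cM = c(spos, qpos),
      type = rep(c("snp", "qtl"), c(snp_per[c], qtl_per[c])))
  }
  map <- do.call(rbind, pieces)
  map <- map[order(map$chr, map$pos_cM), ]
  map$locus <- seq_len(nrow(map))
  idx_in_chr <- stats::ave(map$locus, map$chr, map$type, FUN = seq_along)
  map$name <- sprintf("%s_%d_%d", map$type, map$chr, idx_in_chr)
  rownames(map) <- NULL
  map[, c("locus", "name", "chr", "pos_cM", "type")]
}

## Per-chromosome index/position info used by meiosis.
.chr_info <- function(map) {
  lapply(split(seq_len(nrow(map)), map$chr), function(idx) {
    list(idx = idx, pos_M = map$pos_cM[idx] / 100,
         len_M = max(map$pos_cM[idx]) / 100)
  })
}

## Produce one gamete per entry of `parents` (row indices into H1/H2).
## Crossover counts are Poisson(chromosome length in Morgans), positions
## uniform, no interference (Haldane model).
.make_gametes <- function(H1, H2, parents, info) {
  n <- length(parents)
  L <- ncol(H1)
  out <- matrix(0L, n, L)
  nchr <- length(info)
  lens <- vapply(info, `[[`, numeric(1), "len_M")
  K <- matrix(stats::rpois(n * nchr, rep(lens, each = n)), n, nchr)
  S <- matrix(sample(c(0L, 1L), n * nchr, replace = TRUE), n, nchr)
  src <- integer(L)
  for (g in seq_len(n)) {
    for (c in seq_len(nchr)) {
      ch <- info[[c]]
      if (K[g, c] == 0L) {
        src[ch$idx] <- S[g, c]
      } else {
        xo <- sort(stats::runif(K[g, c], 0, ch$len_M))
        src[ch$idx] <- (S[g, c] + findInterval(ch$pos_M, xo)) %% 2L
      }
    }
    row <- H1[parents[g], ]
    swap <- src == 1L
    if (any(swap)) row[swap] <- H2[parents[g], ][swap]
    out[g, ] <- row
  }
  out
}

## One generation of random mating producing n_off diploid offspring.
.random_mating_gen <- function(H1, H2, n_off, info) {
  N <- nrow(H1)
  sires <- sample.int(N, n_off, replace = TRUE)
  dams <- sample.int(N, n_off, replace = TRUE)
  clash <- dams == sires
  while (any(clash)) {
    dams[clash] <- sample.int(N, sum(clash), replace = TRUE)
    clash <- dams == sires
  }
  list(H1 = .make_gametes(H1, H2, sires, info),
       H2 = .make_gametes(H1, H2, dams, info))
}

## ---- historical phase ------------------------------------------------------

#' Simulate the historical (burn-in) phase and return a founder pool
#'
#' Founder allele frequencies are drawn from U(0.05, 0.95) and haplotypes
#' sampled independently per locus (linkage equilibrium); the configured
#' phases of random mating then build linkage disequilibrium through drift
#' and recombination.  Smaller and longer bottleneck phases give more LD
#' between adjacent markers (see \code{\link{calibrate_ld}}).  Loci fixed by
#' drift are dropped from the pool so every returned locus segregates.
#'
#' @param spec a \code{\link{genome_spec}}.
#' @param schedule a \code{\link{population_schedule}}; only its
#'   \code{historical} table is used here.
#' @param seed integer seed; the pool is a pure function of
#'   (spec, schedule, seed).
#' @return an object of class \code{founder_pool}: list with the marker map
#'   (fixed loci removed), haplotype matrices \code{H1}/\code{H2}
#'   (individuals x loci, 0/1), allele frequencies \code{freq}, and the
#'   number of loci dropped as monomorphic.
#' @export
sim_founders <- function(spec, schedule, seed) {
  stopifnot(inherits(spec, "genome_spec"), inherits(schedule, "pop_schedule"))
  set.seed(as.integer(seed))
  map <- .build_map(spec)
  info <- .chr_info(map)
  L <- nrow(map)
  hist <- schedule$historical
  N0 <- as.integer(hist$size[1])
  if (N0 < 2) .fail("historical population size must be at least 2")
  p0 <- stats::runif(L, 0.05, 0.95)
  H1 <- matrix(stats::rbinom(N0 * L, 1L, rep(p0, each = N0)), N0, L)
  H2 <- matrix(stats::rbinom(N0 * L, 1L, rep(p0, each = N0)), N0, L)
  for (ph in seq_len(nrow(hist))) {
    gens <- hist$generations[ph]
    size <- as.integer(hist$size[ph])
    if (size < 2) .fail("historical population size must be at least 2")
    for (g in seq_len(gens)) {
      off <- .random_mating_gen(H1, H2, size, info)
      H1 <- off$H1
      H2 <- off$H2
    }
  }
  freq <- colMeans(H1 + H2) / 2
  keep <- freq > 0 & freq < 1
  if (!any(keep))
    .fail("all loci were fixed during burn-in (monomorphic genome); shorten the bottleneck")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    map <- map[keep, ]
    map$locus <- seq_len(nrow(map))
    rownames(map) <- NULL
    H1 <- H1[, keep, drop = FALSE]
    H2 <- H2[, keep, drop = FALSE]
    freq <- freq[keep]
  }
  structure(list(map = map, H1 = H1, H2 = H2, freq = unname(freq),
                 spec = spec, schedule = schedule, seed = as.integer(seed),
                 n_dropped = n_dropped),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf(paste0("Founder pool: %d individuals, %d segregating loci ",
                     "(%d SNP, %d QTL), %d fixed loci dropped\n"),
              nrow(x$H1), nrow(x$map), sum(x$map$type == "snp"),
              sum(x$map$type == "qtl"), x$n_dropped))
  invisible(x)
}

## ---- trait standardization -------------------------------------------------

#' Rescale raw QTL effects to hit the target heritability
#'
#' Multiplies the raw additive effects by the single positive constant that
#' makes the sample variance of true breeding values in the base generation
#' equal to \code{h2 * var_p}, and sets the residual variance to
#' \code{var_p * (1 - h2)}.
#'
#' @param raw_effects numeric vector of raw per-QTL additive effects.
#' @param qtl_geno base-generation QTL dosage matrix
#'   (individuals x QTL, 0/1/2).
#' @param h2 target heritability.
#' @param var_p target phenotypic variance.
#' @return list with \code{effects} (rescaled), \code{sigma2_e},
#'   \code{scale}, \code{h2} and \code{var_p}.
#' @export
#' @examples
#' g <- matrix(rbinom(200, 2, 0.5), 100, 2)
#' st <- standardize_trait(c(1, -2), g, h2 = 0.3, var_p = 1)
#' var(drop(g %*% st$effects))  # = 0.3
standardize_trait <- function(raw_effects, qtl_geno, h2, var_p) {
  qtl_geno <- as.matrix(qtl_geno)
  if (length(raw_effects) != ncol(qtl_geno))
    .fail("one raw effect per QTL column is required")
  if (!all(is.finite(raw_effects))) .fail("raw effects must be finite")
  v <- stats::var(drop(qtl_geno %*% raw_effects))
  if (!is.finite(v) || v <= 0)
    .fail("cannot standardize: no genetic variance at the QTL in the base generation")
  scale <- sqrt(h2 * var_p / v)
  if (h2 == 0) scale <- 0
  list(effects = raw_effects * scale,
       sigma2_e = var_p * (1 - h2),
       scale = scale, h2 = h2, var_p = var_p)
}

## ---- selected phase --------------------------------------------------------

## criterion values used to rank selection candidates
.selection_criterion <- function(selection, phen, ebv) {
  switch(selection,
         phenotype = phen,
         pedigree_index = ebv,
         random = stats::runif(length(phen)))
}

#' Breed selected generations from a founder pool
#'
#' Draws the founder cohort (generation 0) from the pool, assigns QTL
#' effects (Gamma magnitudes, random signs, standardized in the founder
#' cohort), and breeds \code{n_generations} discrete offspring cohorts.
#' Each generation every breeding female produces one progeny by a randomly
#' assigned breeding male; the configured fractions of breeding males and
#' females are then replaced by the top-ranking offspring of that generation
#' (truncation selection on the configured criterion, poorest current
#' breeders culled).
#'
#' @param founders a \code{\link{founder_pool}}.
#' @param schedule a \code{\link{population_schedule}}.
#' @param trait a \code{\link{trait_architecture}}.
#' @param seed integer seed for this phase.
#' @return an object of class \code{gs_cohort}: marker map; \code{base},
#'   \code{train} and \code{valid} cohorts (each with ids, SNP dosage matrix,
#'   \code{tbv}, \code{phenotype}, \code{sex}, \code{generation}); the full
#'   pedigree; the realized trait (effects, residual variance); and the mean
#'   TBV per generation.
#' @export
sim_generations <- function(founders, schedule, trait, seed) {
  stopifnot(inherits(founders, "founder_pool"),
            inherits(schedule, "pop_schedule"),
            inherits(trait, "trait_arch"))
  set.seed(as.integer(seed))
  map <- founders$map
  info <- .chr_info(map)
  snp_idx <- which(map$type == "snp")
  qtl_idx <- which(map$type == "qtl")
  if (length(qtl_idx) == 0) .fail("no segregating QTL in the founder pool")
  n_m <- schedule$founder_males
  n_f <- schedule$founder_females
  pool_n <- nrow(founders$H1)
  if (pool_n < n_m + n_f)
    .fail("founder pool too small: %d individuals for %d founders",
          pool_n, n_m + n_f)

  pick <- sample.int(pool_n, n_m + n_f)
  H1 <- founders$H1[pick, , drop = FALSE]
  H2 <- founders$H2[pick, , drop = FALSE]
  sex <- rep(c(1L, 2L), c(n_m, n_f))       # 1 = male, 2 = female

  nq <- length(qtl_idx)
  raw <- stats::rgamma(nq, shape = trait$gamma_shape) *
    sample(c(-1, 1), nq, replace = TRUE)
  qtl_geno <- H1[, qtl_idx, drop = FALSE] + H2[, qtl_idx, drop = FALSE]
  arch <- standardize_trait(raw, qtl_geno, trait$h2, trait$var_p)
  sde <- sqrt(arch$sigma2_e)

  n0 <- n_m + n_f
  tbv <- drop(qtl_geno %*% arch$effects)
  phen <- trait$mean + tbv + stats::rnorm(n0, 0, sde)
  ebv <- trait$h2 * (phen - mean(phen))    # founder index = h2 * deviation
  ids <- seq_len(n0)
  ped <- data.frame(id = ids, sire = 0L, dam = 0L, sex = sex, generation = 0L)
  next_id <- n0 + 1L

  cohort_of <- function(rows, ids, tbv, phen, sex, gen) {
    g <- H1[rows, snp_idx, drop = FALSE] + H2[rows, snp_idx, drop = FALSE]
    rownames(g) <- ids
    colnames(g) <- map$name[snp_idx]
    list(ids = ids, geno = g, tbv = tbv, phenotype = phen, sex = sex,
         generation = gen)
  }
  base <- cohort_of(seq_len(n0), ids, tbv, phen, sex, 0L)

  crit <- .selection_criterion(schedule$selection, phen, ebv)
  cur <- list(H1 = H1, H2 = H2, id = ids, sex = sex, crit = crit,
              ebv = ebv, phen = phen)
  n_rep_m <- round(schedule$male_replacement * n_m)
  n_rep_f <- round(schedule$female_replacement * n_f)
  gen_mean_tbv <- c(`0` = mean(tbv))
  train <- valid <- NULL

  for (gen in seq_len(schedule$n_generations)) {
    dam_rows <- which(cur$sex == 2L)
    male_rows <- which(cur$sex == 1L)
    n_off <- length(dam_rows)
    sire_rows <- sample(male_rows, n_off, replace = TRUE)
    G1 <- .make_gametes(cur$H1, cur$H2, sire_rows, info)
    G2 <- .make_gametes(cur$H1, cur$H2, dam_rows, info)
    off_sex <- sample(c(1L, 2L), n_off, replace = TRUE)
    off_qtl <- G1[, qtl_idx, drop = FALSE] + G2[, qtl_idx, drop = FALSE]
    off_tbv <- drop(off_qtl %*% arch$effects)
    off_phen <- trait$mean + off_tbv + stats::rnorm(n_off, 0, sde)
    pa <- 0.5 * (cur$ebv[sire_rows] + cur$ebv[dam_rows])
    off_ebv <- pa + trait$h2 * (off_phen - mean(off_phen))
    off_ids <- seq.int(next_id, length.out = n_off)
    next_id <- next_id + n_off
    ped <- rbind(ped, data.frame(id = off_ids, sire = cur$id[sire_rows],
                                 dam = cur$id[dam_rows], sex = off_sex,
                                 generation = gen))
    gen_mean_tbv <- c(gen_mean_tbv, stats::setNames(mean(off_tbv), gen))

    keep_cohort <- gen %in% c(schedule$training_generation,
                              schedule$validation_generation)
    if (keep_cohort) {
      g <- G1[, snp_idx, drop = FALSE] + G2[, snp_idx, drop = FALSE]
      rownames(g) <- off_ids
      colnames(g) <- map$name[snp_idx]
      co <- list(ids = off_ids, geno = g, tbv = off_tbv,
                 phenotype = off_phen, sex = off_sex, generation = gen)
      if (gen == schedule$training_generation) train <- co
      if (gen == schedule$validation_generation) valid <- co
    }

    if (gen < schedule$n_generations) {
      off_crit <- .selection_criterion(schedule$selection, off_phen, off_ebv)
      cand_m <- which(off_sex == 1L)
      cand_f <- which(off_sex == 2L)
      if (length(cand_m) < n_rep_m || length(cand_f) < n_rep_f)
        .fail("generation %d: not enough selection candidates (%d males, %d females) for replacement rates",
              gen, length(cand_m), length(cand_f))
      new_m <- cand_m[order(off_crit[cand_m], decreasing = TRUE)][seq_len(n_rep_m)]
      new_f <- cand_f[order(off_crit[cand_f], decreasing = TRUE)][seq_len(n_rep_f)]
      keep_m <- male_rows[order(cur$crit[male_rows],
                                decreasing = TRUE)][seq_len(n_m - n_rep_m)]
      keep_f <- dam_rows[order(cur$crit[dam_rows],
                               decreasing = TRUE)][seq_len(n_f - n_rep_f)]
      keep_rows <- c(keep_m, keep_f)
      new_rows <- c(new_m, new_f)
      cur <- list(
        H1 = rbind(cur$H1[keep_rows, , drop = FALSE],
                   G1[new_rows, , drop = FALSE]),
        H2 = rbind(cur$H2[keep_rows, , drop = FALSE],
                   G2[new_rows, , drop = FALSE]),
        id = c(cur$id[keep_rows], off_ids[new_rows]),
        sex = c(cur$sex[keep_rows], off_sex[new_rows]),
        crit = c(cur$crit[keep_rows], off_crit[new_rows]),
        ebv = c(cur$ebv[keep_rows], off_ebv[new_rows]),
        phen = c(cur$phen[keep_rows], off_phen[new_rows]))
    }
  }

  structure(list(map = map, base = base, train = train, valid = valid,
                 pedigree = ped,
                 trait = c(arch, list(mean = trait$mean,
                                      qtl_loci = qtl_idx,
                                      qtl_names = map$name[qtl_idx],
                                      qtl_var = arch$effects^2 *
                                        apply(qtl_geno, 2, stats::var))),
                 gen_mean_tbv = gen_mean_tbv,
                 spec = founders$spec, schedule = schedule,
                 seed = as.integer(seed)),
            class = "gs_cohort")
}

#' Simulate a structured population end to end
#'
#' Convenience wrapper running \code{\link{sim_founders}} then
#' \code{\link{sim_generations}} with stage seeds derived from one master
#' seed (\code{\link{derive_seeds}}).
#'
#' @param spec a \code{\link{genome_spec}}.
#' @param schedule a \code{\link{population_schedule}}.
#' @param trait a \code{\link{trait_architecture}}.
#' @param seed master seed.
#' @return a \code{gs_cohort}, see \code{\link{sim_generations}}.
#' @export
#' @examples
#' \donttest{
#' sim <- sim_population(genome_spec(2, 50, 100, 10),
#'                       population_schedule(
#'                         historical = data.frame(generations = 5, size = 40),
#'                         founder_males = 5, founder_females = 30,
#'                         n_generations = 3),
#'                       trait_architecture(), seed = 1)
#' sim
#' }
sim_population <- function(spec = genome_spec(),
                           schedule = population_schedule(),
                           trait = trait_architecture(), seed) {
  seeds <- derive_seeds(seed, 2)
  founders <- sim_founders(spec, schedule, seeds[1])
  sim_generations(founders, schedule, trait, seeds[2])
}

#' @export
print.gs_cohort <- function(x, ...) {
  cat(sprintf(paste0("Simulated population: %d SNPs, %d QTL, h2 = %g\n",
                     "  base %d | training (G%d) %d | validation (G%d) %d ",
                     "individuals\n  mean TBV by generation: %s\n"),
              sum(x$map$type == "snp"), sum(x$map$type == "qtl"),
              x$trait$h2, length(x$base$ids),
              x$train$generation, length(x$train$ids),
              x$valid$generation, length(x$valid$ids),
              paste(sprintf("%.3f", x$gen_mean_tbv), collapse = " ")))
  invisible(x)
}

## ---- LD measurement and calibration ----------------------------------------

#' Mean linkage disequilibrium between adjacent markers
#'
#' Computes r-squared as the squared Pearson correlation of allele dosages
#' for every pair of adjacent SNPs within a chromosome.  Pairs with a
#' monomorphic member are skipped (and counted).
#'
#' @param geno dosage matrix (individuals x loci).
#' @param map marker map with one row per column of \code{geno}, columns
#'   \code{chr} and \code{pos_cM} (rows of type \code{"qtl"}, if a
#'   \code{type} column is present, are ignored).
#' @return list with \code{mean_r2}, a per-pair table \code{pairs}
#'   (chr, locus indices, r2), and \code{n_skipped}.
#' @export
measure_adjacent_ld <- function(geno, map) {
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map))
    .fail("map must have one row per genotype column")
  use <- if ("type" %in% names(map)) which(map$type == "snp")
         else seq_len(nrow(map))
  res <- lapply(split(use, map$chr[use]), function(idx) {
    idx <- idx[order(map$pos_cM[idx])]
    if (length(idx) < 2) return(NULL)
    i1 <- idx[-length(idx)]
    i2 <- idx[-1]
    x <- geno[, i1, drop = FALSE]
    y <- geno[, i2, drop = FALSE]
    mx <- colMeans(x); my <- colMeans(y)
    sxy <- colMeans(x * y) - mx * my
    sx2 <- colMeans(x^2) - mx^2
    sy2 <- colMeans(y^2) - my^2
    ok <- sx2 > 0 & sy2 > 0
    r2 <- ifelse(ok, sxy^2 / (sx2 * sy2), NA_real_)
    data.frame(chr = map$chr[i1], locus1 = i1, locus2 = i2, r2 = r2)
  })
  pairs <- do.call(rbind, res)
  if (is.null(pairs) || nrow(pairs) == 0)
    .fail("need at least 2 SNPs on some chromosome")
  list(mean_r2 = mean(pairs$r2, na.rm = TRUE), pairs = pairs,
       n_skipped = sum(is.na(pairs$r2)))
}

#' Calibrate the burn-in schedule against a target level of LD
#'
#' Runs the historical phase over a grid of bottleneck sizes and burn-in
#' lengths (followed by a short expansion to \code{expand_size}) on a reduced
#' genome and reports the realized mean adjacent-marker r-squared.  Longer
#' burn-in at smaller size gives more LD; pick the row closest to the target
#' and use it in \code{\link{population_schedule}}.  Note that adjacent-pair
#' LD depends on the marker spacing of \code{spec}, so calibrate at the
#' spacing you will simulate at.
#'
#' @param spec genome used for calibration (a reduced genome with the target
#'   marker spacing is enough).
#' @param sizes bottleneck population sizes to try.
#' @param generations burn-in lengths to try.
#' @param expand_size size of the short (2-generation) expansion appended
#'   after the bottleneck.
#' @param seed master seed; one replicate per grid cell per seed offset.
#' @param reps replicates per cell.
#' @return data.frame with columns size, generations, rep, mean_r2.
#' @export
calibrate_ld <- function(spec, sizes, generations, expand_size = 200,
                         seed = 1, reps = 1) {
  grid <- expand.grid(size = sizes, generations = generations,
                      rep = seq_len(reps))
  seeds <- derive_seeds(seed, nrow(grid))
  grid$mean_r2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sch <- population_schedule(
      historical = data.frame(generations = c(grid$generations[i], 2L),
                              size = c(grid$size[i], expand_size)),
      founder_males = 2, founder_females = 2, n_generations = 1,
      training_generation = 1, validation_generation = 1)
    fp <- sim_founders(spec, sch, seeds[i])
    geno <- fp$H1 + fp$H2
    grid$mean_r2[i] <- measure_adjacent_ld(geno, fp$map)$mean_r2
  }
  grid
}

#' Population presets for the two LD regimes
#'
#' Ready-made (spec, schedule, trait) bundles for a moderate-LD population
#' (adjacent-marker r-squared near 0.3) and a high-LD population (near 0.7)
#' at desk scale, calibrated with \code{\link{calibrate_ld}} at the preset's
#' marker spacing.
#'
#' @param name which preset.
#' @param n_snps,n_qtl panel size (defaults give a 0.2 cM marker spacing).
#' @param founder_males,founder_females,n_generations cohort sizes passed to
#'   \code{\link{population_schedule}}.
#' @return list with elements \code{spec}, \code{schedule}, \code{trait}.
#' @export
pop_preset <- function(name = c("moderate_ld", "high_ld"),
                       n_snps = 5000, n_qtl = 200,
                       founder_males = 100, founder_females = 2000,
                       n_generations = 7) {
  name <- match.arg(name)
  hist <- switch(name,
    moderate_ld = data.frame(generations = c(45L, 2L),
                             size = c(50L, founder_males + founder_females)),
    high_ld = data.frame(generations = c(80L, 2L),
                         size = c(20L, founder_males + founder_females)))
  list(spec = genome_spec(n_chromosomes = 10, chromosome_length_cM = 100,
                          n_snps = n_snps, n_qtl = n_qtl),
       schedule = population_schedule(
         historical = hist,
         founder_males = founder_males, founder_females = founder_females,
         n_generations = n_generations),
       trait = trait_architecture(h2 = 0.3, var_p = 1))
}
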