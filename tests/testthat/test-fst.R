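test_that("phenotype tails follow the empirical quantile rule", {
  tg <- partition_by_phenotype(1:100)
  expect_identical(tg$S1, 1:5)
  expect_identical(tg$S2, 96:100)
  expect_identical(sort(c(tg$S1, tg$S0, tg$S2)), 1:100)

  ## the reference cohort size: 15,000 phenotypes give 1,500 tail animals
  set.seed(1)
  tg2 <- partition_by_phenotype(rnorm(15000))
  expect_identical(tg2$n_S1 + tg2$n_S2, 1500L)
  expect_identical(tg2$n_S1, 750L)

  ## ties broken by index, deterministically
  y <- rep(c(1, 2), each = 50)
  tg3 <- partition_by_phenotype(y)
  expect_identical(tg3$S1, 1:5)

  expect_error(partition_by_phenotype(1:100, 0.5, 0.5), "smaller")
  expect_error(partition_by_phenotype(rep(1, 100)), "constant")
  expect_error(partition_by_phenotype(1:10, 0.5, 0.51), "middle group")
})

test_that("allele frequencies and heterozygosity come from dosage counts", {
  f <- allele_frequencies(matrix(c(2, 1, 1, 0, 0), 5, 1))
  expect_equal(f$p, 0.4)
  expect_equal(f$het, 0.48)
  expect_equal(allele_frequencies(matrix(c(2, 2, 2), 3, 1))$het, 0)
  expect_equal(allele_frequencies(matrix(c(0, 1, 2), 3, 1))$p, 0.5)
  ## missing genotypes are excluded per locus
  f2 <- allele_frequencies(matrix(c(2, NA, 0, NA), 4, 1))
  expect_equal(f2$p, 0.5)
  expect_equal(f2$n_called, 2)
})

test_that("Nei FST between tails reproduces hand-computed scores", {
  ## build a cohort whose tails have prescribed allele frequencies:
  ## 10 in each tail
  mk <- function(p1, p2) {
    g1 <- c(rep(2, round(10 * p1)), rep(0, 10 - round(10 * p1)))
    g2 <- c(rep(2, round(10 * p2)), rep(0, 10 - round(10 * p2)))
    matrix(c(g1, rep(1, 10), g2), ncol = 1)
  }
  y <- c(1:10, 11:20, 21:30)
  tg <- partition_by_phenotype(y, lower = 1 / 3, upper = 2 / 3)
  expect_identical(tg$n_S1, 10L)

  ## p1 = 0.8, p2 = 0.2 (homozygote mixture): pbar = 0.5, H_T = 0.5,
  ## H_S = mean(2*.8*.2, 2*.2*.8) = 0.32, FST = 0.36... but with pure
  ## homozygotes H_S uses the expected 2pq of each tail, not observed het
  s <- fst_scores(mk(0.8, 0.2), tg)
  expect_equal(s$H_T, 0.5)
  expect_equal(s$H_S, 0.32)
  expect_equal(s$fst, 0.36)

  ## no differentiation
  expect_equal(fst_scores(mk(0.3, 0.3), tg)$fst, 0)
  ## fixed difference
  s2 <- fst_scores(mk(1, 0), tg)
  expect_equal(s2$H_S, 0)
  expect_equal(s2$fst, 1)
  ## monomorphic across both tails: flagged, scored 0
  s3 <- fst_scores(mk(1, 1), tg)
  expect_equal(s3$fst, 0)
  expect_true(s3$monomorphic)
})

test_that("FST scores stay in [0, 1] for arbitrary genotype input", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(40:120, 1)
    m <- sample(5:40, 1)
    g <- matrix(rbinom(n * m, 2, runif(m, 0.02, 0.98)), n, m, byrow = TRUE)
    tg <- partition_by_phenotype(rnorm(n), 0.1, 0.9)
    s <- fst_scores(g, tg)
    expect_true(all(s$fst >= 0 & s$fst <= 1))
    expect_true(all(s$H_S <= s$H_T + 1e-12))
  }
})

test_that("top-k selection ranks by score with genome-order tie-breaks", {
  sc <- structure(data.frame(locus = 1:3, name = as.character(1:3),
                             H_T = 0.5, H_S = 0.3,
                             fst = c(0.1, 0.9, 0.5), monomorphic = FALSE),
                  class = c("fst_scores", "data.frame"))
  expect_identical(select_top_k(sc, 2)$loci, c(2L, 3L))
  expect_identical(select_top_k(sc, 3)$loci, 1:3)
  sc$fst <- c(0.4, 0.4, 0.4)
  expect_identical(select_top_k(sc, 2)$loci, c(1L, 2L))
  expect_error(select_top_k(sc, 0), "integer")
  expect_error(select_top_k(sc, 4), "exceeds")
})

test_that("random selection is uniform and seed-reproducible", {
  s1 <- select_random_k(100, 10, seed = 5)
  s2 <- select_random_k(100, 10, seed = 5)
  expect_identical(s1$loci, s2$loci)
  expect_identical(select_random_k(20, 20, seed = 1)$loci, 1:20)
  expect_error(select_random_k(10, 11, seed = 1), "exceeds")

  ## inclusion frequency over many seeds is ~ k / panel
  inc <- rowSums(vapply(1:400, function(s)
    tabulate(select_random_k(50, 10, seed = s)$loci, 50), numeric(50)))
  expect_equal(mean(inc / 400), 0.2, tolerance = 1e-12)  # exact by counting
  expect_true(all(abs(inc / 400 - 0.2) < 0.1))
})

test_that("tail FST tracks large QTL and collapses under permutation", {
  sim <- small_cohort()
  smap <- sim$map[sim$map$type == "snp", ]
  qmap <- sim$map[sim$map$type == "qtl", ]
  geno <- sim$train$geno
  y <- sim$train$phenotype
  tg <- partition_by_phenotype(y)
  s_true <- fst_scores(geno, tg)

  ## SNPs within 2 cM of a top-decile-effect QTL
  eff <- sim$trait$effects
  top_q <- qmap[order(-abs(eff))[seq_len(ceiling(nrow(qmap) / 10))], ]
  near <- vapply(seq_len(nrow(smap)), function(i) {
    any(top_q$chr == smap$chr[i] & abs(top_q$pos_cM - smap$pos_cM[i]) < 2)
  }, logical(1))
  expect_gt(sum(near), 3)

  ratio_true <- mean(s_true$fst[near]) / mean(s_true$fst)
  expect_gt(ratio_true, 1)

  ## permuting phenotypes destroys the association
  set.seed(123)
  ratio_perm <- replicate(5, {
    tgp <- partition_by_phenotype(sample(y))
    sp <- fst_scores(geno, tgp)
    mean(sp$fst[near]) / mean(sp$fst)
  })
  expect_lt(mean(ratio_perm), ratio_true)
  expect_lt(abs(mean(ratio_perm) - 1), 0.35)
})
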