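test_that("REML maximum agrees with a brute-force likelihood grid (n = 8)", {
  set.seed(21)
  n <- 8
  M <- matrix(rbinom(n * 40, 2, 0.5), n, 40,
              dimnames = list(paste0("id", 1:n), NULL))
  K <- suppressMessages(grm_vanraden(M, ridge = 1e-6))
  u <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * sqrt(0.5)
  y <- setNames(3 + u + rnorm(n, 0, sqrt(0.5)), rownames(K))
  fit <- gblup(y, K)
  X <- matrix(1, n, 1)

  grid <- expand.grid(su = seq(0.02, 3, by = 0.02),
                      se = seq(0.02, 3, by = 0.02))
  ll <- mapply(function(su, se) dense_reml_ll(su, se, unname(y), X, K),
               grid$su, grid$se)
  best <- grid[which.max(ll), ]
  ## the fitted maximum dominates the whole grid...
  expect_gte(fit$loglik, max(ll) - 1e-8)
  ## ...and sits within one grid step of the grid argmax
  expect_lt(abs(fit$vc[1] - best$su), 0.021)
  expect_lt(abs(fit$vc[2] - best$se), 0.021)
  ## and the internal likelihood matches the dense formula where evaluated
  expect_equal(dense_reml_ll(fit$vc[1], fit$vc[2], unname(y), X, K),
               fit$loglik, tolerance = 1e-6)
})

test_that("GEBVs from the rotated solver match a dense MME solve", {
  set.seed(22)
  n <- 30
  K <- structured_kernel(n = n, n_snps = 200, seed = 8)
  u <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * sqrt(0.4)
  y <- setNames(5 + u + rnorm(n, 0, sqrt(0.6)), rownames(K))
  fit <- gblup(y, K)
  su <- fit$vc[1]; se <- fit$vc[2]
  X <- matrix(1, n, 1)

  ## Henderson's mixed-model equations, solved densely
  Ki <- solve(K)
  lhs <- rbind(cbind(crossprod(X) / se, t(X) / se),
               cbind(X / se, diag(n) / se + Ki / su))
  rhs <- c(crossprod(X, unname(y)) / se, unname(y) / se)
  sol <- solve(lhs, rhs)
  expect_equal(unname(fit$beta), unname(sol[1]), tolerance = 1e-8)
  expect_equal(unname(fit$u[names(y)]), unname(sol[-1]), tolerance = 1e-8)

  ## and the direct GLS formula for u
  V <- su * K + se * diag(n)
  b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, unname(y)))
  u_gls <- drop(su * K %*% solve(V, unname(y) - drop(X %*% b)))
  expect_equal(unname(fit$u[names(y)]), unname(u_gls), tolerance = 1e-8)
})

test_that("AI-REML recovers simulated variance components", {
  n <- 400
  K <- structured_kernel(n = n, n_snps = 500, seed = 6)
  L <- t(chol(K + diag(1e-8, n)))
  set.seed(31)
  reps <- 20
  est <- t(replicate(reps, {
    y <- setNames(drop(L %*% rnorm(n)) * sqrt(0.3) +
                    rnorm(n, 0, sqrt(0.7)), rownames(K))
    fit <- gblup(y, K)
    c(fit$vc, var = var(unname(y)))
  }))
  se_u <- sd(est[, 1]) / sqrt(reps)
  se_e <- sd(est[, 2]) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 0.3), 3 * se_u + 0.01)
  expect_lt(abs(mean(est[, 2]) - 0.7), 3 * se_e + 0.01)
  ## variance partition sanity: s2u + s2e tracks the phenotypic variance
  expect_equal(mean(est[, 1] + est[, 2]), mean(est[, 3]), tolerance = 0.05)
})

test_that("pure noise drives the genetic variance to the boundary", {
  n <- 200
  K <- structured_kernel(n = n, n_snps = 300, seed = 9)
  set.seed(41)
  y <- setNames(rnorm(n), rownames(K))
  fit <- gblup(y, K)
  expect_lt(fit$vc[1], 0.05)
  ## full shrinkage: GEBVs collapse toward zero with sigma2_u
  expect_lt(max(abs(fit$u)), max(0.2, 10 * fit$vc[1]))
})

test_that("REML is invariant to phenotype location shifts", {
  n <- 120
  K <- structured_kernel(n = n, n_snps = 300, seed = 12)
  set.seed(51)
  y <- setNames(drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) +
                  rnorm(n), rownames(K))
  f1 <- gblup(y, K)
  f2 <- gblup(y + 1000, K)
  expect_equal(f1$vc, f2$vc, tolerance = 1e-6)
  expect_equal(unname(f2$beta[1] - f1$beta[1]), 1000, tolerance = 1e-6)
})

test_that("unphenotyped individuals are predicted through the kernel", {
  n <- 150
  K <- structured_kernel(n = n, n_snps = 400, seed = 13)
  set.seed(61)
  u <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * sqrt(0.5)
  y_all <- u + rnorm(n, 0, sqrt(0.5))
  train <- rownames(K)[1:100]
  valid <- rownames(K)[101:150]
  fit <- gblup(setNames(y_all[1:100], train), K)
  pred <- predict(fit, valid)
  expect_length(pred, 50)
  expect_gt(cor(pred, u[101:150]), 0.3)
  expect_error(predict(fit, "nobody"), "absent")
})

test_that("gblup object methods are coherent", {
  n <- 60
  K <- structured_kernel(n = n, n_snps = 200, seed = 14)
  set.seed(71)
  y <- setNames(drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) + rnorm(n),
                rownames(K))
  fit <- gblup(y, K)
  expect_s3_class(fit, "gblup")
  expect_output(print(fit), "AI-REML")
  s <- summary(fit)
  expect_output(print(s), "Heritability")
  expect_equal(unname(coef(fit)), unname(fit$beta))
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  sims <- simulate(fit, nsim = 3, seed = 1, K = K)
  expect_equal(dim(sims), c(n, 3L))
  ## same seed, same draws
  expect_equal(sims, simulate(fit, nsim = 3, seed = 1, K = K))
})

test_that("accuracy is a guarded Pearson correlation", {
  x <- rnorm(50)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)
  expect_error(accuracy(x[1:2], x[1:2]), "at least 3")
  expect_error(accuracy(rep(1, 10), rnorm(10)), "zero-variance")
  set.seed(81)
  expect_lt(abs(accuracy(rnorm(5000), rnorm(5000))), 0.05)
})

test_that("k-fold cross-validation partitions and reproduces", {
  n <- 80
  K <- structured_kernel(n = n, n_snps = 200, seed = 15)
  set.seed(91)
  u <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * sqrt(0.5)
  y <- setNames(u + rnorm(n, 0, sqrt(0.5)), rownames(K))
  cv1 <- kfold_cv(y, K, folds = 5, seed = 4, truth = setNames(u, names(y)))
  cv2 <- kfold_cv(y, K, folds = 5, seed = 4, truth = setNames(u, names(y)))
  expect_identical(cv1$assignment, cv2$assignment)
  expect_equal(cv1$mean_accuracy, cv2$mean_accuracy)
  expect_true(max(cv1$folds$n) - min(cv1$folds$n) <= 1)
  expect_equal(sum(cv1$folds$n), n)
  expect_error(kfold_cv(y, K, folds = 1), "integer")
  ## adjusted-phenotype mode runs without truth
  cv3 <- kfold_cv(y, K, folds = 4, seed = 2)
  expect_length(cv3$folds$accuracy, 4)
})
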