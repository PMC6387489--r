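## ---------------------------------------------------------------------------
## Single-kernel GBLUP: y = X b + u + e,  u ~ N(0, K sigma2_u),
## e ~ N(0, I sigma2_e), fitted by AI-REML with an EM-REML fallback.
##
## The kernel K is eigendecomposed once; all REML quantities (log-likelihood,
## score, average-information matrix) are then evaluated in the rotated basis
## where the variance matrix is diagonal, so each iteration costs O(n p).
## ---------------------------------------------------------------------------

## Core REML engine on the rotated problem.  Returns variance components,
## fixed effects, Py (rotated), log-likelihood, AI matrix and trajectory.
.reml_ai <- function(y, X, K, init = NULL, max_iter = 200L,
                     tol_par = 1e-8, tol_ll = 1e-6, floor = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  ## quantities at a given (su, se)
  eval_at <- function(su, se) {
    v <- su * d + se
    vinv <- 1 / v
    XtVX <- crossprod(Xt, Xt * vinv)
    R <- chol(XtVX)
    b <- backsolve(R, forwardsolve(t(R), crossprod(Xt, yt * vinv)))
    Py <- vinv * (yt - drop(Xt %*% b))
    ldXtVX <- 2 * sum(log(diag(R)))
    ll <- -0.5 * (sum(log(v)) + ldXtVX + sum(yt * Py))
    Pf <- function(f) {                 # apply the projection P to a vector
      vf <- vinv * f
      vf - vinv * drop(Xt %*% backsolve(R, forwardsolve(t(R),
                                                        crossprod(Xt, vf))))
    }
    W <- Xt %*% backsolve(R, forwardsolve(t(R), diag(p)))
    Bii <- rowSums(W * Xt) * vinv^2     # diag of V^-1 X (X'V^-1X)^-1 X' V^-1
    trPD <- sum(d * vinv) - sum(d * Bii)
    trPI <- sum(vinv) - sum(Bii)
    list(su = su, se = se, v = v, vinv = vinv, b = drop(b), Py = Py,
         ll = ll, Pf = Pf, trPD = trPD, trPI = trPI)
  }

  ## starting values: split the OLS residual variance
  r0 <- stats::lm.fit(X, y)$residuals
  v0 <- stats::var(r0)
  theta <- init %||% c(0.5 * v0, 0.5 * v0)
  theta <- pmax(theta, floor)
  st <- eval_at(theta[1], theta[2])
  traj <- data.frame(iter = 0L, sigma2_u = theta[1], sigma2_e = theta[2],
                     loglik = st$ll, step = "init")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fu <- d * st$Py
    fe <- st$Py
    score <- 0.5 * c(sum(st$Py * fu) - st$trPD,
                     sum(st$Py * fe) - st$trPI)
    Pfu <- st$Pf(fu)
    Pfe <- st$Pf(fe)
    AI <- 0.5 * matrix(c(sum(fu * Pfu), sum(fu * Pfe),
                         sum(fu * Pfe), sum(fe * Pfe)), 2, 2)
    step <- "ai"
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    prop <- if (is.null(delta)) c(-1, -1) else theta + delta
    if (any(prop < floor)) {
      ## EM-REML fallback: always moves uphill and keeps components positive
      step <- "em"
      prop <- theta + theta^2 *
        c(sum(st$Py * fu) - st$trPD, sum(st$Py * fe) - st$trPI) / n
      prop <- pmax(prop, floor)
    }
    new <- eval_at(prop[1], prop[2])
    ## guard: if the AI step decreased the likelihood, halve it
    h <- 0
    while (new$ll < st$ll - 1e-10 && step == "ai" && h < 20) {
      delta <- delta / 2
      prop <- pmax(theta + delta, floor)
      new <- eval_at(prop[1], prop[2])
      h <- h + 1
      step <- "ai-halved"
    }
    rel <- max(abs(prop - theta) / pmax(abs(theta), 1e-8))
    dll <- abs(new$ll - st$ll)
    theta <- prop
    st <- new
    traj <- rbind(traj, data.frame(iter = iter, sigma2_u = theta[1],
                                   sigma2_e = theta[2], loglik = st$ll,
                                   step = step))
    if (rel < tol_par || dll < tol_ll) { converged <- TRUE; break }
  }
  ## asymptotic variance of the estimates from the final AI matrix
  fu <- d * st$Py; fe <- st$Py
  AI <- 0.5 * matrix(c(sum(fu * st$Pf(fu)), sum(fu * st$Pf(fe)),
                       sum(fu * st$Pf(fe)), sum(fe * st$Pf(fe))), 2, 2)
  vcov_vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  Py_orig <- drop(U %*% st$Py)
  list(sigma2_u = theta[1], sigma2_e = theta[2], beta = st$b,
       loglik = st$ll, iterations = iter, converged = converged,
       trajectory = traj, Py = Py_orig, vcov_vc = vcov_vc,
       boundary = any(theta <= 10 * floor), n = n, p = p)
}

#' Fit a GBLUP mixed model by AI-REML
#'
#' Fits \code{y = X b + u + e} with \code{u ~ N(0, K sigma2_u)} and
#' \code{e ~ N(0, I sigma2_e)} by restricted maximum likelihood using the
#' average-information algorithm, falling back on an EM-REML step whenever
#' an AI update would leave the parameter space (components are floored at
#' 1e-10).  Iteration stops when the relative change in the components falls
#' below \code{tol_par} or the log-likelihood change below \code{tol_ll}.
#' Individuals present in \code{K} but absent from \code{y} (e.g. a
#' genotyped but unphenotyped validation cohort) receive breeding-value
#' predictions through their covariance with the phenotyped records.
#'
#' @param y named numeric vector of phenotypes; names must appear among the
#'   rownames of \code{K}.  Unnamed vectors are matched positionally to the
#'   first rows of \code{K}.
#' @param K relationship kernel (e.g. \code{\link{grm_vanraden}}) covering
#'   all individuals, phenotyped or not.
#' @param X fixed-effect design matrix for the phenotyped records (default:
#'   intercept only).  Rank-deficient columns are dropped with a message.
#' @param init optional starting values \code{c(sigma2_u, sigma2_e)}.
#' @param max_iter,tol_par,tol_ll iteration controls.
#' @return an object of class \code{gblup}: variance components and their
#'   asymptotic covariance, heritability, fixed effects, GEBVs \code{u} for
#'   every individual in \code{K}, fitted values and residuals for the
#'   phenotyped records, the REML log-likelihood, convergence information
#'   and the iteration trajectory.
#' @seealso \code{\link{accuracy}}, \code{\link{kfold_cv}}
#' @export
#' @examples
#' set.seed(1)
#' M <- matrix(rbinom(50 * 80, 2, 0.5), 50, 80,
#'             dimnames = list(paste0("id", 1:50), NULL))
#' G <- grm_vanraden(M)
#' u <- drop(chol(G + diag(1e-6, 50)) %*% rnorm(50)) * sqrt(0.3)
#' y <- setNames(10 + u + rnorm(50, 0, sqrt(0.7)), rownames(G))
#' fit <- gblup(y, G)
#' fit
gblup <- function(y, K, X = NULL, init = NULL, max_iter = 200L,
                  tol_par = 1e-8, tol_ll = 1e-6) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    .fail("K must be a square relationship matrix")
  ids_all <- rownames(K) %||% as.character(seq_len(nrow(K)))
  rownames(K) <- colnames(K) <- ids_all
  if (is.null(names(y))) {
    if (length(y) > nrow(K)) .fail("more phenotypes than rows in K")
    names(y) <- ids_all[seq_along(y)]
  }
  miss <- setdiff(names(y), ids_all)
  if (length(miss))
    .fail("individual(s) absent from K: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 4) .fail("need at least 4 phenotyped individuals")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) .fail("X must have one row per phenotyped record")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    message(sprintf("gblup: dropping %d rank-deficient fixed-effect column(s)",
                    length(drop_cols)))
    X <- X[, -drop_cols, drop = FALSE]
  }
  ti <- match(names(y), ids_all)
  Ktt <- K[ti, ti, drop = FALSE]
  fit <- .reml_ai(unname(y), X, Ktt, init = init, max_iter = max_iter,
                  tol_par = tol_par, tol_ll = tol_ll)
  u <- drop(fit$sigma2_u * K[, ti, drop = FALSE] %*% fit$Py)
  names(u) <- ids_all
  fitted <- drop(X %*% fit$beta) + u[names(y)]
  h2 <- fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e)
  structure(list(
    vc = c(sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e),
    h2 = h2, vcov_vc = fit$vcov_vc,
    beta = stats::setNames(fit$beta, colnames(X)),
    u = u, y = y, X = X,
    fitted = stats::setNames(fitted, names(y)),
    residuals = stats::setNames(unname(y) - fitted, names(y)),
    loglik = fit$loglik, iterations = fit$iterations,
    converged = fit$converged, boundary = fit$boundary,
    trajectory = fit$trajectory,
    ids = ids_all, ids_train = names(y),
    call = match.call()), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit (AI-REML)\n")
  cat(sprintf("  records: %d phenotyped / %d in kernel\n",
              length(x$y), length(x$ids)))
  cat(sprintf("  sigma2_u = %.4f, sigma2_e = %.4f, h2 = %.3f\n",
              x$vc[1], x$vc[2], x$h2))
  cat(sprintf("  logLik = %.3f, %d iterations, %s%s\n", x$loglik,
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary) " (boundary estimate)" else ""))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov_vc), 0))
  g <- object$vc[1]; e <- object$vc[2]; s <- g + e
  grad <- c(e, -g) / s^2                   # d h2 / d(sigma2_u, sigma2_e)
  h2_se <- sqrt(max(0, drop(t(grad) %*% object$vcov_vc %*% grad)))
  out <- list(vc = data.frame(component = c("sigma2_u", "sigma2_e"),
                              estimate = unname(object$vc), se = se),
              h2 = object$h2, h2_se = h2_se, beta = object$beta,
              loglik = object$loglik, iterations = object$iterations,
              converged = object$converged, boundary = object$boundary,
              n = length(object$y))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("GBLUP mixed model, AI-REML variance components\n\n")
  print(x$vc, row.names = FALSE, digits = 4)
  cat(sprintf("\nHeritability: %.3f (se %.3f)\n", x$h2, x$h2_se))
  cat("\nFixed effects:\n")
  print(x$beta, digits = 4)
  cat(sprintf("\nlogLik %.3f after %d iterations (%s)\n", x$loglik,
              x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2L,
            nobs = length(object$y), class = "logLik")
}

#' Predicted breeding values from a GBLUP fit
#'
#' @param object a \code{\link{gblup}} fit.
#' @param ids individuals to return (default: all individuals in the
#'   kernel).  Unknown ids are an error.
#' @param ... unused.
#' @return named vector of GEBVs.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$u)
  ids <- as.character(ids)
  miss <- setdiff(ids, object$ids)
  if (length(miss))
    .fail("individual(s) absent from K: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  object$u[ids]
}

#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$u[x$ids_train], x$y, xlab = "GEBV",
                 ylab = "phenotype",
                 main = "GBLUP: phenotype vs estimated breeding value", ...)
  graphics::abline(stats::lm(x$y ~ x$u[x$ids_train]), col = 2)
  invisible(x)
}

#' Simulate phenotypes from a fitted GBLUP model
#'
#' Draws new phenotype vectors for the phenotyped records from
#' \code{N(X b, K sigma2_u + I sigma2_e)} at the REML estimates (parametric
#' bootstrap).  Requires the kernel rows of the training individuals, which
#' are re-derived from the stored fit.
#'
#' @param object a \code{gblup} fit carrying its training kernel.
#' @param nsim number of replicate vectors.
#' @param seed optional seed.
#' @param K the kernel used in the original fit (kept out of the object to
#'   save memory).
#' @param ... unused.
#' @return data.frame with \code{nsim} columns.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, K, ...) {
  if (!is.null(seed)) set.seed(seed)
  ti <- match(object$ids_train, rownames(K))
  if (anyNA(ti)) .fail("K does not cover the training individuals")
  n <- length(ti)
  V <- object$vc[1] * K[ti, ti] + diag(object$vc[2], n)
  L <- chol(V + diag(1e-10, n))
  mu <- drop(object$X %*% object$beta)
  out <- as.data.frame(mu + t(L) %*% matrix(stats::rnorm(n * nsim), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$ids_train
  out
}

#' Accuracy of genomic prediction
#'
#' Pearson correlation between predicted breeding values and a reference:
#' either true breeding values (simulation) or phenotypes adjusted for the
#' estimated fixed effects (real data).
#'
#' @param gebv named vector of predictions (validation individuals).
#' @param reference matching vector of TBVs or adjusted phenotypes.
#' @return correlation in [-1, 1].
#' @export
accuracy <- function(gebv, reference) {
  if (length(gebv) != length(reference))
    .fail("gebv and reference must have equal length")
  if (length(gebv) < 3) .fail("need at least 3 validation individuals")
  if (stats::sd(gebv) == 0 || stats::sd(reference) == 0)
    .fail("zero-variance input; accuracy undefined")
  stats::cor(gebv, reference)
}

#' k-fold cross-validation of GBLUP
#'
#' Records are assigned to folds deterministically from the seed (fold sizes
#' differ by at most one); each fold is held out once, the model refitted on
#' the remainder, and the held-out individuals' GEBVs correlated with either
#' their true breeding values (if \code{truth} is supplied) or their
#' phenotypes adjusted for the estimated fixed effects.
#'
#' @param y named phenotype vector.
#' @param K relationship kernel covering all records.
#' @param X optional fixed-effect design (rows matching \code{y}).
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param truth optional named vector of true breeding values.
#' @return list with the per-fold table (\code{fold}, \code{n},
#'   \code{accuracy}), the mean accuracy, and the fold assignment.
#' @export
kfold_cv <- function(y, K, X = NULL, folds = 5, seed = 1, truth = NULL) {
  folds <- .check_count(folds, "folds", min = 2L)
  n <- length(y)
  if (n < folds) .fail("more folds than records")
  if (is.null(names(y))) names(y) <- rownames(K)[seq_len(n)]
  set.seed(as.integer(seed))
  assign <- sample(rep(seq_len(folds), length.out = n))
  res <- data.frame(fold = seq_len(folds), n = NA_integer_,
                    accuracy = NA_real_)
  for (f in seq_len(folds)) {
    hold <- which(assign == f)
    fit <- gblup(y[-hold], K, X = if (is.null(X)) NULL
                 else X[-hold, , drop = FALSE])
    pred <- predict(fit, names(y)[hold])
    ref <- if (!is.null(truth)) truth[names(y)[hold]]
           else {
             Xh <- if (is.null(X)) matrix(1, length(hold), 1)
                   else X[hold, , drop = FALSE]
             y[hold] - drop(Xh %*% fit$beta)
           }
    res$n[f] <- length(hold)
    res$accuracy[f] <- accuracy(pred, ref)
  }
  list(folds = res, mean_accuracy = mean(res$accuracy), assignment = assign)
}
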