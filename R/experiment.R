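## ---------------------------------------------------------------------------
## Experiment driver: simulate, score, select, relate, fit, evaluate —
## over a ladder of panel densities, FST-based vs random, replicated.
## ---------------------------------------------------------------------------

#' Configuration of a prioritization experiment
#'
#' Bundles the simulator settings with the analysis grid.  The density
#' ladder is expressed as fractions of the realized SNP panel so the same
#' relative grid applies at any scale.  Per replicate the training set is a
#' random \code{train_frac} of the training generation and the validation
#' set a random \code{valid_frac} of the validation generation; FST scores
#' are computed on the training set's phenotype tails, and the random
#' subsets are redrawn per replicate.
#'
#' @param spec,schedule,trait simulator settings (see
#'   \code{\link{sim_population}}).
#' @param ladder density ladder as fractions of the panel size.
#' @param methods subset-selection methods to compare.
#' @param replicates number of simulation replicates.
#' @param lower,upper phenotype-tail quantiles for FST scoring.
#' @param train_frac,valid_frac sampled fractions of the training and
#'   validation generations.
#' @param similarity also compute the mean IBS similarity per cell (costs
#'   one dense matrix product per cell).
#' @param seed master seed; everything else is derived from it.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(spec = genome_spec(),
                              schedule = population_schedule(),
                              trait = trait_architecture(),
                              ladder = c(0.00625, 0.025, 0.1),
                              methods = c("fst", "random"),
                              replicates = 5,
                              lower = 0.05, upper = 0.95,
                              train_frac = 2 / 3, valid_frac = 1 / 3,
                              similarity = TRUE, seed = 1) {
  stopifnot(inherits(spec, "genome_spec"), inherits(schedule, "pop_schedule"),
            inherits(trait, "trait_arch"))
  if (any(ladder <= 0 | ladder > 1))
    .fail("ladder entries must be fractions in (0, 1]")
  methods <- match.arg(methods, c("fst", "random"), several.ok = TRUE)
  .check_count(replicates, "replicates")
  .check_frac(train_frac, "train_frac")
  .check_frac(valid_frac, "valid_frac")
  structure(list(spec = spec, schedule = schedule, trait = trait,
                 ladder = sort(unique(ladder)), methods = methods,
                 replicates = as.integer(replicates),
                 lower = lower, upper = upper,
                 train_frac = train_frac, valid_frac = valid_frac,
                 similarity = isTRUE(similarity), seed = as.integer(seed)),
            class = "experiment_config")
}

## one (method, k) cell on a prepared replicate
.run_cell <- function(prep, method, k, sel_seed, compute_sim) {
  sel <- switch(method,
                fst = select_top_k(prep$scores, k),
                random = select_random_k(ncol(prep$geno), k, sel_seed),
                full = structure(list(loci = seq_len(ncol(prep$geno)),
                                      method = "full",
                                      k = ncol(prep$geno)),
                                 class = "marker_selection"))
  G <- grm_vanraden(prep$geno, sel)
  fit <- gblup(prep$y_train, G)
  acc <- accuracy(predict(fit, prep$valid_ids), prep$tbv_valid)
  sim_mean <- sim_se <- NA_real_
  if (compute_sim) {
    S <- genomic_similarity(prep$geno, sel)
    ms <- mean_offdiag(S)
    sim_mean <- ms$mean
    sim_se <- ms$se
  }
  data.frame(method = method, k = sel$k,
             k_frac = sel$k / ncol(prep$geno),
             similarity = sim_mean, similarity_se = sim_se,
             sigma2_u = unname(fit$vc[1]), sigma2_e = unname(fit$vc[2]),
             h2 = fit$h2, accuracy = acc, converged = fit$converged)
}

## simulate one replicate and precompute everything the cells share
.prepare_replicate <- function(config, seed) {
  seeds <- derive_seeds(seed, 4)
  sim <- sim_population(config$spec, config$schedule, config$trait, seeds[1])
  n_tr <- max(2, round(config$train_frac * length(sim$train$ids)))
  n_va <- max(3, round(config$valid_frac * length(sim$valid$ids)))
  set.seed(seeds[2])
  tr <- sort(sample(seq_along(sim$train$ids), n_tr))
  va <- sort(sample(seq_along(sim$valid$ids), n_va))
  geno <- rbind(sim$train$geno[tr, , drop = FALSE],
                sim$valid$geno[va, , drop = FALSE])
  groups <- partition_by_phenotype(sim$train$phenotype[tr],
                                   config$lower, config$upper)
  scores <- fst_scores(sim$train$geno[tr, , drop = FALSE], groups)
  list(sim = sim, geno = geno,
       y_train = stats::setNames(sim$train$phenotype[tr],
                                 as.character(sim$train$ids[tr])),
       valid_ids = as.character(sim$valid$ids[va]),
       tbv_valid = sim$valid$tbv[va],
       scores = scores, sel_seed = seeds[3])
}

#' Run the full prioritization experiment
#'
#' Per replicate: simulate a population, score SNPs by phenotype-tail FST
#' on the training sample, then for every (method, k) cell on the density
#' ladder select markers, build the VanRaden G over training plus
#' validation, fit GBLUP by AI-REML, and correlate the validation GEBVs
#' with their true breeding values; a full-panel cell is always included.
#' A failing cell is recorded with NA results and a message instead of
#' aborting the grid.  The whole run is a pure function of the master seed.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param verbose print progress per replicate.
#' @return object of class \code{gs_experiment}: the per-cell \code{rows}
#'   table and the config.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rep_seeds <- derive_seeds(config$seed, config$replicates)
  rows <- list()
  failures <- character()
  for (r in seq_len(config$replicates)) {
    if (verbose) message(sprintf("replicate %d/%d", r, config$replicates))
    prep <- .prepare_replicate(config, rep_seeds[r])
    panel <- ncol(prep$geno)
    cells <- rbind(expand.grid(method = config$methods,
                               density = config$ladder,
                               stringsAsFactors = FALSE),
                   data.frame(method = "full", density = 1))
    cells$k <- pmax(1L, pmin(panel, round(cells$density * panel)))
    for (i in seq_len(nrow(cells))) {
      res <- tryCatch(
        .run_cell(prep, cells$method[i], cells$k[i],
                  prep$sel_seed + i, config$similarity),
        error = function(e) {
          failures <<- c(failures, sprintf(
            "replicate %d, %s k=%d: %s", r, cells$method[i], cells$k[i],
            conditionMessage(e)))
          data.frame(method = cells$method[i], k = cells$k[i],
                     k_frac = cells$k[i] / panel, similarity = NA_real_,
                     similarity_se = NA_real_, sigma2_u = NA_real_,
                     sigma2_e = NA_real_, h2 = NA_real_,
                     accuracy = NA_real_, converged = NA)
        })
      res$density <- cells$density[i]
      res$replicate <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(failures))
    warning(sprintf("%d cell(s) failed:\n%s", length(failures),
                    paste(failures, collapse = "\n")))
  out <- do.call(rbind, rows)
  out <- out[, c("replicate", "method", "density",
                 setdiff(names(out), c("replicate", "method", "density")))]
  structure(list(rows = out, config = config, failures = failures),
            class = "gs_experiment")
}

#' @export
print.gs_experiment <- function(x, ...) {
  cat(sprintf("Prioritization experiment: %d replicates x %d cells\n",
              x$config$replicates, nrow(x$rows) / x$config$replicates))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Aggregate an experiment over replicates
#'
#' @param object a \code{gs_experiment}.
#' @param ... unused.
#' @return data.frame keyed by (method, k) with the mean and SD over
#'   replicates of similarity, variance components and accuracy.
#' @export
summary.gs_experiment <- function(object, ...) {
  r <- object$rows
  key <- interaction(r$method, r$density, drop = TRUE)
  agg <- function(v, f) tapply(v, key, f, na.rm = TRUE)
  first <- !duplicated(key)
  out <- data.frame(method = r$method[first], density = r$density[first])
  out <- out[order(out$method, out$density), ]
  key_lv <- interaction(out$method, out$density, drop = TRUE)
  out$k <- round(as.numeric(agg(r$k, mean)[key_lv]))
  for (v in c("similarity", "sigma2_u", "sigma2_e", "h2", "accuracy")) {
    out[[paste0(v, "_mean")]] <- as.numeric(agg(r[[v]], mean)[key_lv])
    out[[paste0(v, "_sd")]] <- as.numeric(agg(r[[v]], stats::sd)[key_lv])
  }
  rownames(out) <- NULL
  out
}

#' Write report tables and an accuracy plot for an experiment
#'
#' Emits tab-separated tables in the shapes of the classic reporting:
#' genomic similarity by density and method, variance components by density
#' and method, accuracy by density and method, plus a per-replicate raw
#' table and an accuracy-versus-density plot (one line per method).
#'
#' @param experiment a \code{gs_experiment}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
report_tables <- function(experiment, dir) {
  stopifnot(inherits(experiment, "gs_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(experiment)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                       sep = "\t")
    path
  }
  paths <- c(
    wr(s[, c("method", "density", "k", "similarity_mean", "similarity_sd")],
       "similarity.tsv"),
    wr(s[, c("method", "density", "k", "sigma2_u_mean", "sigma2_u_sd",
             "sigma2_e_mean", "sigma2_e_sd", "h2_mean", "h2_sd")],
       "variance_components.tsv"),
    wr(s[, c("method", "density", "k", "accuracy_mean", "accuracy_sd")],
       "accuracy.tsv"),
    wr(experiment$rows, "replicates.tsv"))
  plot_path <- file.path(dir, "accuracy_vs_density.pdf")
  grDevices::pdf(plot_path, width = 6, height = 4.5)
  on.exit(grDevices::dev.off())
  methods <- unique(s$method)
  cols <- stats::setNames(seq_along(methods) + 1L, methods)
  graphics::plot(NA, xlim = range(s$k), ylim = range(s$accuracy_mean,
                                                     na.rm = TRUE),
                 log = "x", xlab = "number of SNPs (log scale)",
                 ylab = "accuracy",
                 main = "Prediction accuracy vs panel density")
  for (m in methods) {
    sm <- s[s$method == m, ]
    graphics::lines(sm$k, sm$accuracy_mean, type = "b", col = cols[m],
                    pch = 19)
  }
  graphics::legend("bottomright", legend = methods, col = cols, lty = 1,
                   pch = 19, bty = "n")
  invisible(c(paths, plot = plot_path))
}
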